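#' One-sided hypergeometric gene-set enrichment with BH adjustment
#'
#' For every term the overlap with the query is tested against the
#' hypergeometric null: population = background, successes = term genes
#' present in the background, draws = query size,
#' \eqn{p = P(X \ge \mathrm{overlap})}. p values are adjusted across all
#' tested terms with the Benjamini-Hochberg step-up procedure.
#'
#' Query genes absent from the background are dropped with a warning and
#' do not count toward overlaps or the query size.
#'
#' @param query character vector of gene symbols.
#' @param collection a \code{\link{read_gmt}} collection (named list).
#' @param background character vector, the gene universe.
#' @return data.frame with columns \code{term}, \code{overlap_count},
#'   \code{term_size}, \code{query_size}, \code{background_size},
#'   \code{p}, \code{adjusted_p}, sorted by \code{p} ascending.
#' @export
hypergeometric_enrichment <- function(query, collection, background) {
  if (length(query) == 0L) stop("empty query gene set")
  if (length(background) == 0L) stop("empty background gene set")
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) absent from the background were dropped")
    query <- intersect(query, background)
  }
  if (length(query) == 0L) stop("no query gene lies in the background")

  nbg <- length(background)
  nq <- length(query)
  rows <- lapply(names(collection), function(nm) {
    term <- intersect(collection[[nm]], background)
    ov <- length(intersect(term, query))
    m <- length(term)
    p <- if (ov == 0L) 1 else
      stats::phyper(ov - 1, m = m, n = nbg - m, k = nq, lower.tail = FALSE)
    data.frame(term = nm, overlap_count = ov, term_size = m,
               query_size = nq, background_size = nbg, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$adjusted_p <- stats::p.adjust(tab$p, method = "BH")
  tab[order(tab$p, tab$term), , drop = FALSE]
}

#' Terms significantly enriched in the seed genes
#'
#' @param seeds seed gene symbols.
#' @param collection gene-set collection.
#' @param background gene universe.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return Character vector of term names with \code{adjusted_p <= alpha}.
#' @export
seed_enriched_terms <- function(seeds, collection, background, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  tab <- hypergeometric_enrichment(seeds, collection, background)
  hits <- tab$term[tab$adjusted_p <= alpha]
  if (length(hits) == 0L)
    stop("no term enriched in the seeds at adjusted p <= ", alpha,
         "; the biological criterion is undefined for this collection")
  hits
}

#' Sliding-window enrichment profile along a DIAMOnD ranking
#'
#' At each iteration t the window holds the ranked genes at positions
#' \code{max(1, t - window + 1) .. t} (a shrinking head window for
#' t < window, so the profile is defined from iteration 1). Window members
#' annotated to any seed-enriched term are true positives, and the
#' per-iteration enrichment p value is the hypergeometric upper tail of
#' observing at least that many annotated genes in a draw of the window
#' size from the background.
#'
#' @param ranking a \code{diamond_ranking} (or its \code{gene} column order).
#' @param enriched_genes union of genes annotated to any seed-enriched term.
#' @param window window size; the convention is the number of in-network
#'   seed genes.
#' @param background gene universe for the test.
#' @return data.frame of class \code{boundary_report}: columns
#'   \code{iteration}, \code{window_size}, \code{true_positives}, \code{p}.
#' @export
sliding_window_significance <- function(ranking, enriched_genes, window,
                                        background) {
  genes <- if (is.data.frame(ranking)) ranking$gene else as.character(ranking)
  if (length(genes) < 1L) stop("empty ranking")
  stopifnot(window >= 1L)
  background <- unique(background)
  nbg <- length(background)
  m <- length(intersect(enriched_genes, background))
  annotated <- genes %in% enriched_genes

  n <- length(genes)
  tp <- integer(n); wsize <- integer(n); p <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - window + 1L)
    wsize[t] <- t - lo + 1L
    tp[t] <- sum(annotated[lo:t])
    p[t] <- if (tp[t] == 0L) 1 else
      stats::phyper(tp[t] - 1, m = m, n = nbg - m, k = wsize[t],
                    lower.tail = FALSE)
  }
  structure(
    data.frame(iteration = seq_len(n), window_size = wsize,
               true_positives = tp, p = p),
    class = c("boundary_report", "data.frame"),
    window = window, background_size = nbg, annotated_in_background = m
  )
}

#' Select the module boundary from an enrichment-p profile
#'
#' The candidate list is bounded at the largest iteration whose enrichment
#' p value is at or below the threshold (the plateau of candidates with
#' direct biological evidence); 0 when no iteration qualifies.
#'
#' @param p per-iteration enrichment p values (or a \code{boundary_report}).
#' @param threshold significance level (default 0.01).
#' @return Integer cutoff index (0 if none significant).
#' @export
select_module_boundary <- function(p, threshold = 0.01) {
  if (is.data.frame(p)) p <- p$p
  if (length(p) == 0L) stop("empty enrichment-p sequence")
  stopifnot(threshold > 0, threshold < 1)
  hits <- which(p <= threshold)
  if (length(hits) == 0L) 0L else max(hits)
}
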
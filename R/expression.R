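#' Expression set: genes x samples with group and batch labels
#'
#' Container for a log-scale expression matrix. Rows are gene symbols,
#' columns are samples; every sample carries a \code{group} label
#' (\code{"case"} or \code{"control"}) and a \code{batch} label.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample ids).
#' @param group character vector, one of \code{"case"}/\code{"control"}
#'   per sample.
#' @param batch character vector, one batch label per sample.
#' @return An object of class \code{expr_set}.
#' @export
expr_set <- function(values, group, batch = rep("b1", ncol(values))) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in expression matrix; collapse probes first")
  if (length(group) != ncol(values) || length(batch) != ncol(values))
    stop("group/batch length must match the sample count")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  structure(
    list(values = values, group = as.character(group), batch = as.character(batch)),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples (%d case / %d control; batches: %s)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control"),
              paste(unique(x$batch), collapse = ", ")))
  invisible(x)
}

#' Collapse probe-level measurements to gene symbols
#'
#' Multiple probes mapping to the same symbol are collapsed to their
#' arithmetic mean, per sample. Probes without a mapping are dropped with
#' a logged count. Gene rows are returned in lexicographic order.
#'
#' @param values probes x samples numeric matrix (rownames = probe ids).
#' @param probe_map named character vector, probe id -> gene symbol.
#' @param group,batch per-sample labels forwarded to \code{\link{expr_set}}.
#' @return An \code{\link{expr_set}} on gene symbols.
#' @export
collapse_probes <- function(values, probe_map, group, batch = rep("b1", ncol(values))) {
  values <- as.matrix(values)
  probes <- rownames(values)
  if (is.null(probes)) stop("probe matrix must have probe rownames")
  sym <- unname(probe_map[probes])
  keep <- !is.na(sym) & nzchar(sym)
  n_drop <- sum(!keep)
  if (!any(keep)) stop("no probe maps to a gene symbol")
  if (n_drop > 0L)
    ns_log("collapse_probes", "dropped %d unmapped probe(s)", n_drop)
  v <- values[keep, , drop = FALSE]
  sym <- sym[keep]
  # rowsum() aggregates by symbol in one pass; divide by probe multiplicity
  sums <- rowsum(v, group = sym, reorder = TRUE)
  counts <- as.vector(table(sym)[rownames(sums)])
  collapsed <- sums / counts
  collapsed <- collapsed[order(rownames(collapsed)), , drop = FALSE]
  expr_set(collapsed, group = group, batch = batch)
}

#' Merge two expression sets on shared gene symbols
#'
#' Genes are intersected by symbol; samples are concatenated and the batch
#' label of each sample is set to the source dataset's name.
#'
#' @param a,b \code{\link{expr_set}} objects collapsed to gene symbols.
#' @param names length-2 character, batch labels for the two sources.
#' @return An \code{\link{expr_set}} on the common genes.
#' @export
merge_batches <- function(a, b, names = c("batch1", "batch2")) {
  stopifnot(inherits(a, "expr_set"), inherits(b, "expr_set"))
  if (length(intersect(colnames(a$values), colnames(b$values))) > 0L)
    stop("sample ids of the two datasets must be disjoint")
  common <- intersect(rownames(a$values), rownames(b$values))
  if (length(common) == 0L) stop("no gene symbols shared between the two datasets")
  common <- sort(common)
  ns_log("merge_batches", "%d shared genes, %d + %d samples",
         length(common), ncol(a$values), ncol(b$values))
  expr_set(
    cbind(a$values[common, , drop = FALSE], b$values[common, , drop = FALSE]),
    group = c(a$group, b$group),
    batch = c(rep(names[1L], ncol(a$values)), rep(names[2L], ncol(b$values)))
  )
}

#' Remove batch effects from an expression set
#'
#' The default \code{method = "eb"} applies the parametric empirical-Bayes
#' location-scale model of ComBat (Johnson et al. 2007) via
#' \code{sva::ComBat}. \code{method = "standardize"} instead equalizes each
#' gene's per-batch mean and standard deviation to the pooled values --
#' a plain location-scale adjustment without variance shrinkage.
#' Genes with zero variance inside some batch are passed through with a
#' location-only adjustment (a warning is raised).
#'
#' @param expr an \code{\link{expr_set}} with a \code{batch} label per sample.
#' @param method \code{"eb"} (ComBat) or \code{"standardize"}.
#' @return An \code{\link{expr_set}} of identical dimensions and labels.
#' @export
batch_correct <- function(expr, method = c("eb", "standardize")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expr_set"))
  batches <- unique(expr$batch)
  if (length(batches) < 2L) {
    ns_log("batch_correct", "single batch; returning input unchanged")
    return(expr)
  }
  tab <- table(expr$batch)
  if (any(tab < 2L))
    stop("every batch needs at least 2 samples; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))

  v <- expr$values
  # zero within-batch variance breaks the scale model; adjust location only
  degenerate <- rep(FALSE, nrow(v))
  for (b in batches) {
    vb <- v[, expr$batch == b, drop = FALSE]
    degenerate <- degenerate | apply(vb, 1L, stats::sd) == 0
  }
  if (any(degenerate))
    warning(sum(degenerate), " gene(s) with zero variance within a batch: ",
            "location-only adjustment applied")

  out <- v
  if (method == "eb") {
    if (!requireNamespace("sva", quietly = TRUE))
      stop("method 'eb' requires the sva package; use method = 'standardize'")
    ok <- !degenerate
    if (any(ok)) {
      out[ok, ] <- suppressMessages(
        sva::ComBat(dat = v[ok, , drop = FALSE], batch = expr$batch,
                    par.prior = TRUE, prior.plots = FALSE)
      )
    }
    if (any(degenerate))
      out[degenerate, ] <- .location_adjust(v[degenerate, , drop = FALSE], expr$batch)
  } else {
    for (i in seq_len(nrow(v))) {
      x <- v[i, ]
      mu <- mean(x); sig <- stats::sd(x)
      for (b in batches) {
        j <- expr$batch == b
        mb <- mean(x[j]); sb <- stats::sd(x[j])
        if (sb > 0 && sig > 0) {
          out[i, j] <- (x[j] - mb) / sb * sig + mu
        } else {
          out[i, j] <- x[j] - mb + mu
        }
      }
    }
  }
  expr_set(out, group = expr$group, batch = expr$batch)
}

# subtract per-batch mean, restore the pooled mean (location-only ComBat fallback)
.location_adjust <- function(v, batch) {
  out <- v
  for (b in unique(batch)) {
    j <- batch == b
    mb <- rowMeans(v[, j, drop = FALSE])
    out[, j] <- v[, j, drop = FALSE] - mb + rowMeans(v)
  }
  out
}

#' Read an expression TSV (first column gene/probe id, rest samples)
#'
#' @param path expression TSV path.
#' @param meta_path TSV with columns \code{sample_id}, \code{group},
#'   \code{batch} supplying the per-sample labels.
#' @return An \code{\link{expr_set}}.
#' @export
read_expression_tsv <- function(path, meta_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1L)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "batch")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  m <- as.matrix(tab)
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata: ",
                       paste(colnames(m)[is.na(idx)], collapse = ", "))
  expr_set(m, group = meta$group[idx], batch = meta$batch[idx])
}

#' Write an expression set to TSV (+ metadata TSV)
#' @param expr an \code{\link{expr_set}}.
#' @param path expression TSV path.
#' @param meta_path metadata TSV path.
#' @export
write_expression_tsv <- function(expr, path, meta_path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(expr$values),
                     group = expr$group, batch = expr$batch)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
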
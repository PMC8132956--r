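#' Per-sample expression unit conversions
#'
#' Pure unit conversions from gene-level fragment counts and effective
#' transcript lengths, matching the quantities reported for the
#' developmental time course: FPKM (fragments per kilobase of transcript per
#' million mapped fragments), TPM (transcripts per million; the within-sample
#' rate-normalized unit, columns sum to 1e6), and TPE (transcripts per
#' embryo) obtained by scaling FPKM by an embryo calibration factor of 60.
#' Fragment-length modelling and effective-length estimation are the
#' quantifier's job upstream; the caller supplies whichever lengths it has.
#'
#' @param counts Non-negative numeric vector of per-gene fragment counts for
#'   one sample.
#' @param eff_lengths Positive numeric vector of per-gene (effective)
#'   transcript lengths in base pairs.
#' @return Numeric vector of the converted unit.
#' @examples
#' compute_fpkm(c(10, 10), c(1000, 2000))  # 500000 250000
#' compute_tpm(c(10, 10), c(1000, 2000))   # 666666.7 333333.3
#' @export
compute_fpkm <- function(counts, eff_lengths) {
  .check_expr_cols(counts, eff_lengths)
  n <- sum(counts)
  if (n == 0) {
    warning("all counts are zero; FPKM column is all zero", call. = FALSE)
    return(rep(0, length(counts)))
  }
  counts / ((eff_lengths / 1000) * (n / 1e6))
}

#' @rdname compute_fpkm
#' @export
compute_tpm <- function(counts, eff_lengths) {
  .check_expr_cols(counts, eff_lengths)
  rate <- counts / eff_lengths
  s <- sum(rate)
  if (s == 0) {
    warning("all counts are zero; TPM column is all zero", call. = FALSE)
    return(rep(0, length(counts)))
  }
  1e6 * rate / s
}

.check_expr_cols <- function(counts, eff_lengths) {
  if (length(counts) != length(eff_lengths)) {
    stop("counts and eff_lengths differ in length")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(eff_lengths <= 0)) stop("effective lengths must be positive")
  invisible(TRUE)
}

#' Convert FPKM to transcripts per embryo
#'
#' Elementwise scaling by the embryo calibration factor (default 60, the
#' S. purpuratus value inherited from the original time-course study).
#'
#' @param fpkm Numeric vector or matrix of FPKM values.
#' @param tpe_factor Calibration factor.
#' @return Same shape as `fpkm`.
#' @export
fpkm_to_tpe <- function(fpkm, tpe_factor = 60) {
  fpkm * tpe_factor
}

#' Build an expression table with derived TPM/FPKM/TPE matrices
#'
#' @param counts Gene-by-sample numeric matrix of fragment counts (rows named
#'   by gene, columns by sample/timepoint, e.g. `"0h"`..`"72h"`).
#' @param eff_lengths Gene-by-sample matrix of effective lengths, or a single
#'   per-gene vector recycled across samples.
#' @param tpe_factor Embryo calibration factor (default 60).
#' @return An `expression_table` with fields `genes`, `samples`, `counts`,
#'   `eff_lengths` and derived matrices `tpm`, `fpkm`, `tpe`.
#' @export
expression_table <- function(counts, eff_lengths, tpe_factor = 60) {
  counts <- as.matrix(counts)
  if (is.null(dim(eff_lengths)) || !identical(dim(eff_lengths), dim(counts))) {
    eff_lengths <- matrix(eff_lengths, nrow = nrow(counts), ncol = ncol(counts),
                          dimnames = dimnames(counts))
  }
  fpkm <- counts
  tpm <- counts
  for (j in seq_len(ncol(counts))) {
    fpkm[, j] <- compute_fpkm(counts[, j], eff_lengths[, j])
    tpm[, j] <- compute_tpm(counts[, j], eff_lengths[, j])
  }
  structure(list(genes = rownames(counts), samples = colnames(counts),
                 counts = counts, eff_lengths = eff_lengths,
                 tpm = tpm, fpkm = fpkm, tpe = fpkm_to_tpe(fpkm, tpe_factor),
                 tpe_factor = tpe_factor),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table>", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; metrics: TPM, FPKM, TPE (factor", x$tpe_factor, ")\n")
  invisible(x)
}

#' Write one expression metric as a gene-by-sample TSV
#'
#' Header row of sample labels preceded by a `gene` column; one metric per
#' file, matching the layout of the published expression tables.
#'
#' @param x An [expression_table()].
#' @param metric One of `"tpm"`, `"fpkm"`, `"tpe"`, `"counts"`.
#' @param path Optional output path.
#' @return The lines, invisibly.
#' @export
write_expression_tsv <- function(x, metric = c("tpm", "tpe", "fpkm", "counts"),
                                 path = NULL) {
  stopifnot(inherits(x, "expression_table"))
  metric <- match.arg(metric)
  m <- x[[metric]]
  genes <- if (is.null(rownames(m))) seq_len(nrow(m)) else rownames(m)
  samples <- if (is.null(colnames(m))) paste0("s", seq_len(ncol(m))) else colnames(m)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(genes[i], format(m[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  .emit_lines(c(paste(c("gene", samples), collapse = "\t"), rows), path)
}
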
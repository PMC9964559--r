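## Tab-separated table contracts shared by the pipeline stages.

#' Read / write an expression table
#'
#' TSV contract: first column `gene_id`, one column per sample,
#' non-negative FPKM values.
#'
#' @param path TSV file.
#' @return gene x sample numeric matrix.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene_id") stop("expression table must start with 'gene_id'")
  if (anyDuplicated(d$gene_id)) stop("duplicate gene ids in ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  if (any(m < 0)) stop("negative expression values in ", path)
  m
}

#' @rdname read_expression
#' @param expr gene x sample matrix.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinetics table
#'
#' TSV contract: `reaction_id`, `kcat_f`, `kcat_b` (turnovers per
#' minute; `kcat_b` may be NA for irreversible reactions), optional
#' `source` (measured|default).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_kinetics <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "kcat_f", "kcat_b")
  if (!all(need %in% names(d))) stop("kinetics table needs columns: ",
                                     paste(need, collapse = ", "))
  if (any(d$kcat_f <= 0, na.rm = TRUE) || any(d$kcat_b <= 0, na.rm = TRUE))
    stop("kcat values must be positive")
  d
}

#' Read clinical survival metadata
#'
#' TSV contract: `sample_id`, `time_months`, `event` (0/1), optional
#' `idh1_mutant` (0/1). Records with missing time or event are dropped
#' with a message (the count is logged), mirroring how cohorts with
#' incomplete follow-up are filtered before analysis.
#'
#' This is also the documented contract for real cohorts: export FPKM
#' from the GDC as `expression.tsv` and the clinical + mutation tables
#' from cBioPortal into these columns; no downloader is provided.
#'
#' @param path TSV file.
#' @param exclude_idh1_mutant drop samples flagged `idh1_mutant == 1`.
#' @return data.frame from [survival_records()] plus `idh1_mutant`.
#' @export
read_clinical <- function(path, exclude_idh1_mutant = TRUE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% names(d))) stop("clinical table needs columns: ",
                                     paste(need, collapse = ", "))
  if (is.null(d$idh1_mutant)) d$idh1_mutant <- 0L
  ok <- stats::complete.cases(d[, c("time_months", "event")]) & d$time_months > 0
  if (any(!ok)) message("read_clinical: dropped ", sum(!ok),
                        " record(s) with missing/invalid follow-up")
  d <- d[ok, , drop = FALSE]
  n_mut <- sum(d$idh1_mutant == 1)
  if (exclude_idh1_mutant && n_mut > 0) {
    message("read_clinical: excluded ", n_mut, " IDH1-mutant sample(s)")
    d <- d[d$idh1_mutant != 1, , drop = FALSE]
  }
  out <- survival_records(d$sample_id, d$time_months, d$event)
  out$idh1_mutant <- as.integer(d$idh1_mutant)
  attr(out, "n_excluded_idh1") <- if (exclude_idh1_mutant) n_mut else 0L
  out
}

#' Read an uptake (medium) table
#'
#' TSV contract: `reaction_id`, `lb`, `ub` in umol/min/L; negative lb
#' means uptake allowed.
#'
#' @param path TSV file.
#' @return data.frame usable by [apply_medium()].
#' @export
read_uptake <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "lb", "ub")
  if (!all(need %in% names(d))) stop("uptake table needs columns: ",
                                     paste(need, collapse = ", "))
  d
}

#' Write a flux matrix as TSV (reaction ids as first column)
#' @param flux reactions x samples matrix.
#' @param path output TSV.
#' @export
write_flux_matrix <- function(flux, path) {
  d <- data.frame(reaction_id = rownames(flux), flux, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_matrix
#' @export
read_flux_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}
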
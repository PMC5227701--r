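# Tab-separated readers/writers for the pipeline's tables. All writers are
# deterministic (fixed column order, no quoting, no row names) so repeated
# runs are byte-identical.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a junction count table to tab-separated files
#'
#' One wide events file (annotation plus `inc_<sample>` / `skip_<sample>`
#' count columns) and a sample sheet.
#'
#' @param table a `JunctionCountTable`.
#' @param counts_path,samples_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_junction_table <- function(table, counts_path, samples_path) {
  wide <- table$events
  inc <- as.data.frame(table$inclusion)
  names(inc) <- paste0("inc_", table$samples$sample_id)
  skp <- as.data.frame(table$skipping)
  names(skp) <- paste0("skip_", table$samples$sample_id)
  .write_tsv(cbind(wide, inc, skp), counts_path)
  .write_tsv(table$samples[, c("sample_id", "genotype", "treatment")],
             samples_path)
  invisible(c(counts_path, samples_path))
}

#' Read a junction count table written by [write_junction_table()]
#' @param counts_path,samples_path input file paths.
#' @return A `JunctionCountTable`.
#' @export
read_junction_table <- function(counts_path, samples_path) {
  wide <- .read_tsv(counts_path)
  samples <- .read_tsv(samples_path)
  inc_cols <- paste0("inc_", samples$sample_id)
  skip_cols <- paste0("skip_", samples$sample_id)
  if (!all(c(inc_cols, skip_cols) %in% names(wide)))
    .stopf("count columns do not match the sample sheet")
  ann <- wide[, setdiff(names(wide), c(inc_cols, skip_cols)), drop = FALSE]
  junction_count_table(ann, samples,
                       as.matrix(wide[, inc_cols, drop = FALSE]),
                       as.matrix(wide[, skip_cols, drop = FALSE]))
}

#' Write context sequences as FASTA (record id = event id)
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_context_fasta <- function(seqs, path) {
  seqs <- seqs[!is.na(seqs)]
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read context sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_context_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Validate pipeline input tables
#'
#' Report-only checks of a junction table and sample sheet: schema, the
#' four-cell condition coverage, count integrality and non-negativity,
#' duplicate ids. Violations are returned, not raised.
#'
#' @param events event annotation data.frame.
#' @param samples sample sheet data.frame.
#' @param inclusion,skipping count matrices.
#' @return Character vector of violations (empty if well-formed).
#' @export
validate_inputs <- function(events, samples, inclusion, skipping) {
  v <- character(0)
  need_s <- c("sample_id", "genotype", "treatment")
  if (!all(need_s %in% names(samples)))
    v <- c(v, sprintf("sample sheet missing column(s): %s",
                      paste(setdiff(need_s, names(samples)), collapse = ", ")))
  else {
    cells <- unique(paste(samples$genotype, samples$treatment, sep = "."))
    missing_cells <- setdiff(condition_levels(), cells)
    if (length(missing_cells))
      v <- c(v, sprintf("incomplete factorial design: missing cell(s) %s",
                        paste(missing_cells, collapse = ", ")))
    if (anyDuplicated(samples$sample_id))
      v <- c(v, "duplicate sample ids")
  }
  if (!all(c("event_id", "event_type") %in% names(events)))
    v <- c(v, "events missing event_id/event_type columns")
  else {
    if (anyDuplicated(events$event_id)) v <- c(v, "duplicate event ids")
    if (!all(events$event_type %in% c("SE", "RI")))
      v <- c(v, "event_type values outside {SE, RI}")
  }
  for (nm in c("inclusion", "skipping")) {
    m <- get(nm)
    bad <- which(m < 0 | m != round(m) | is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      v <- c(v, sprintf("non-integer or negative %s count at row %d, column %d",
                        nm, bad[1, 1], bad[1, 2]))
    if (nrow(m) != nrow(events) || ncol(m) != nrow(samples))
      v <- c(v, sprintf("%s matrix dimensions do not match events x samples", nm))
  }
  v
}
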
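#' Construct a junction count table
#'
#' The central container for event-level splicing data: an event annotation
#' table, a sample sheet assigning each sample to one cell of the
#' \{WT, MT\} x \{Veh, Drug\} design, and matched inclusion/skipping count
#' matrices (events x samples).
#'
#' @param events data.frame with columns `event_id`, `gene_id`, `event_type`
#'   (`"SE"` or `"RI"`), `chrom`, `strand` (`"+"`/`"-"`), coordinate columns
#'   `coord1`..`coord4` (0-based half-open; SE uses all four: upstream-exon
#'   end, cassette start, cassette end, downstream-exon start; RI uses
#'   `coord1`,`coord2` = intron start/end), and effective junction counts
#'   `inc_junction_count`, `skip_junction_count` (defaults SE 2/1, RI 1/1).
#' @param samples data.frame with columns `sample_id`, `genotype`
#'   (`"WT"`/`"MT"`), `treatment` (`"Veh"`/`"Drug"`).
#' @param inclusion,skipping non-negative integer matrices, one row per event
#'   and one column per sample.
#' @return An object of class `JunctionCountTable`.
#' @export
junction_count_table <- function(events, samples, inclusion, skipping) {
  inclusion <- as.matrix(inclusion)
  skipping <- as.matrix(skipping)
  if (!all(c("event_id", "event_type") %in% names(events)))
    .stopf("events must have event_id and event_type columns")
  if (!all(events$event_type %in% c("SE", "RI")))
    .stopf("event_type must be 'SE' or 'RI'")
  if (!all(c("sample_id", "genotype", "treatment") %in% names(samples)))
    .stopf("samples must have sample_id, genotype, treatment columns")
  if (!all(samples$genotype %in% c("WT", "MT")) ||
      !all(samples$treatment %in% c("Veh", "Drug")))
    .stopf("genotype must be WT/MT and treatment Veh/Drug")
  if (anyDuplicated(events$event_id)) .stopf("duplicate event ids")
  if (anyDuplicated(samples$sample_id)) .stopf("duplicate sample ids")
  n_e <- nrow(events); n_s <- nrow(samples)
  if (!all(dim(inclusion) == c(n_e, n_s)) || !all(dim(skipping) == c(n_e, n_s)))
    .stopf("count matrix dimensions must be events x samples")
  if (any(inclusion < 0) || any(skipping < 0) ||
      any(inclusion != round(inclusion)) || any(skipping != round(skipping)))
    .stopf("counts must be non-negative integers")
  if (is.null(events$inc_junction_count))
    events$inc_junction_count <- ifelse(events$event_type == "SE", 2L, 1L)
  if (is.null(events$skip_junction_count))
    events$skip_junction_count <- 1L
  if (any(events$inc_junction_count < 1) || any(events$skip_junction_count < 1))
    .stopf("effective junction counts must be >= 1")
  samples$condition <- paste(samples$genotype, samples$treatment, sep = ".")
  dimnames(inclusion) <- dimnames(skipping) <-
    list(events$event_id, samples$sample_id)
  structure(list(events = events, samples = samples,
                 inclusion = inclusion, skipping = skipping),
            class = "JunctionCountTable")
}

#' @export
print.JunctionCountTable <- function(x, ...) {
  cat(sprintf("JunctionCountTable: %d events (%d SE, %d RI) x %d samples\n",
              nrow(x$events), sum(x$events$event_type == "SE"),
              sum(x$events$event_type == "RI"), nrow(x$samples)))
  print(table(x$samples$condition))
  invisible(x)
}

#' Per cent spliced in from inclusion and skipping counts
#'
#' \eqn{\Psi = (I/n_I) / (I/n_I + S/n_S)} where \eqn{n_I, n_S} are the
#' effective numbers of junctions supporting inclusion and skipping
#' (length normalization in the rMATS convention). Returns `NA` when both
#' counts are zero (no informative reads).
#'
#' @param inclusion,skipping non-negative integer vectors.
#' @param inc_norm,skip_norm positive effective junction counts (recycled).
#' @return Numeric vector of PSI values in \[0, 1\], `NA` where uninformative.
#' @export
compute_psi <- function(inclusion, skipping, inc_norm = 1L, skip_norm = 1L) {
  if (any(inclusion < 0, na.rm = TRUE) || any(skipping < 0, na.rm = TRUE))
    .stopf("counts must be non-negative")
  if (any(inc_norm < 1) || any(skip_norm < 1))
    .stopf("normalization constants must be >= 1")
  i <- inclusion / inc_norm
  s <- skipping / skip_norm
  psi <- i / (i + s)
  psi[(inclusion + skipping) == 0] <- NA_real_
  psi
}

#' Event x sample PSI matrix
#'
#' Applies [compute_psi()] with each event's own effective junction counts.
#'
#' @param table a `JunctionCountTable`.
#' @return Numeric matrix (events x samples) of PSI values, `NA` where a
#'   sample has no informative reads for an event.
#' @export
psi_matrix <- function(table) {
  inc_n <- table$events$inc_junction_count
  skip_n <- table$events$skip_junction_count
  i <- table$inclusion / inc_n
  s <- table$skipping / skip_n
  psi <- i / (i + s)
  psi[(table$inclusion + table$skipping) == 0] <- NA_real_
  psi
}

#' Mean PSI per event within one condition
#'
#' Unweighted mean of per-sample PSI over samples of the condition, ignoring
#' samples with missing PSI; `NA` if every sample is missing.
#'
#' @param table a `JunctionCountTable`.
#' @param condition one of `"WT.Veh"`, `"WT.Drug"`, `"MT.Veh"`, `"MT.Drug"`.
#' @return Named numeric vector over events.
#' @export
condition_mean_psi <- function(table, condition) {
  if (!condition %in% table$samples$condition)
    .stopf("unknown or empty condition label: %s", condition)
  psi <- psi_matrix(table)[, table$samples$condition == condition, drop = FALSE]
  rowMeans(psi, na.rm = TRUE)
}

#' Condition mean PSI for all four cells
#' @param table a `JunctionCountTable`.
#' @return events x 4 matrix with columns [condition_levels()].
#' @export
condition_psi_means <- function(table) {
  out <- vapply(condition_levels(),
                function(cc) condition_mean_psi(table, cc),
                numeric(nrow(table$events)))
  if (nrow(table$events) == 1L)
    out <- matrix(out, 1, dimnames = list(table$events$event_id,
                                          condition_levels()))
  rownames(out) <- table$events$event_id
  out
}

#' Filter events by mean informative coverage
#'
#' Keeps events whose mean total (inclusion + skipping) count across all
#' samples is at least `min_mean_total` (boundary inclusive). This is the
#' "expressed junctions only" filter applied before testing.
#'
#' @param table a `JunctionCountTable`.
#' @param min_mean_total non-negative threshold (default 10, a stand-in:
#'   the source analyses do not state their threshold).
#' @return Filtered `JunctionCountTable`.
#' @export
filter_expressed <- function(table, min_mean_total = 10) {
  if (min_mean_total < 0) .stopf("min_mean_total must be >= 0")
  keep <- rowMeans(table$inclusion + table$skipping) >= min_mean_total
  subset_events(table, keep)
}

#' Subset a junction count table by events
#' @param table a `JunctionCountTable`.
#' @param keep logical/integer/character index over events.
#' @return Subsetted `JunctionCountTable`.
#' @export
subset_events <- function(table, keep) {
  if (is.character(keep)) keep <- match(keep, table$events$event_id)
  structure(list(events = table$events[keep, , drop = FALSE],
                 samples = table$samples,
                 inclusion = table$inclusion[keep, , drop = FALSE],
                 skipping = table$skipping[keep, , drop = FALSE]),
            class = "JunctionCountTable")
}

#' Row-wise z-scoring with population standard deviation
#'
#' Each retained row is centred and scaled to population SD 1 (divisor n,
#' not n-1, the usual heatmap convention). Rows that are constant or contain
#' missing values are dropped and reported.
#'
#' @param values numeric matrix (features x samples), >= 2 columns.
#' @return List with `z` (the z-scored matrix) and `dropped` (character
#'   vector of dropped row names, empty if none).
#' @export
zscore_matrix <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) .stopf("need >= 2 samples to z-score")
  if (is.null(rownames(values))) rownames(values) <- seq_len(nrow(values))
  ok <- stats::complete.cases(values)
  ctr <- values - rowMeans(values)
  popsd <- sqrt(rowMeans(ctr^2))
  ok <- ok & popsd > 1e-12
  list(z = ctr[ok, , drop = FALSE] / popsd[ok],
       dropped = rownames(values)[!ok])
}

#' PCA of samples from a feature x sample value matrix
#'
#' Rows are z-scored (constant/missing rows dropped), then samples are
#' treated as observations in a singular-value decomposition.
#'
#' @param values numeric matrix (features x samples).
#' @param n_components number of components to return (default 3).
#' @return List with `scores` (samples x components), `var_explained`
#'   (non-increasing fractions summing to <= 1) and `dropped` rows.
#' @export
pca_conditions <- function(values, n_components = 3) {
  if (ncol(as.matrix(values)) < 2) .stopf("need >= 2 samples for PCA")
  zs <- zscore_matrix(values)
  if (nrow(zs$z) <= n_components)
    .stopf("need more (non-constant) features than components")
  pc <- stats::prcomp(t(zs$z), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       dropped = zs$dropped)
}
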
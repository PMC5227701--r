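#' Extract the 3' splice-acceptor context of an event
#'
#' Position indexing follows the convention that the exon's first base is
#' position 0; negative positions are intronic, so the acceptor AG occupies
#' -2,-1 and the U2AF1-contacted base is -3. For a + strand event the
#' window is `[acceptor - intronic_len, acceptor + exonic_len)` in 0-based
#' half-open genome coordinates, with the acceptor at the cassette-exon
#' start (SE) or intron end (RI). For a - strand event the mirrored window
#' at the exon's acceptor side is taken and reverse-complemented.
#'
#' @param event one-row data.frame in the [junction_count_table()] event
#'   schema (`chrom`, `strand`, `event_type`, `coord1..coord4`).
#' @param genome a named `Biostrings::DNAStringSet` or named character
#'   vector of chromosome sequences.
#' @param intronic_len,exonic_len window lengths (defaults 20 and 3).
#' @return Context string of length `intronic_len + exonic_len`, or `NA`
#'   (with a warning) when the window runs out of bounds.
#' @export
extract_context <- function(event, genome, intronic_len = 20L,
                            exonic_len = 3L) {
  chrom_seq <- if (inherits(genome, "DNAStringSet"))
    genome[[event$chrom]] else Biostrings::DNAString(genome[[event$chrom]])
  L <- length(chrom_seq)
  if (event$strand == "+") {
    acceptor <- if (event$event_type == "SE") event$coord2 else event$coord2
    start0 <- acceptor - intronic_len
    end0 <- acceptor + exonic_len
    if (start0 < 0 || end0 > L) {
      warning(sprintf("context window out of bounds for %s", event$event_id))
      return(NA_character_)
    }
    as.character(Biostrings::subseq(chrom_seq, start0 + 1L, end0))
  } else {
    # acceptor on - strand: cassette end (SE) or intron start (RI)
    acceptor <- if (event$event_type == "SE") event$coord3 else event$coord1
    start0 <- acceptor - exonic_len
    end0 <- acceptor + intronic_len
    if (start0 < 0 || end0 > L) {
      warning(sprintf("context window out of bounds for %s", event$event_id))
      return(NA_character_)
    }
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(chrom_seq, start0 + 1L, end0)))
  }
}

#' Acceptor contexts for all events of a table
#' @param events event annotation data.frame.
#' @param genome named sequences (see [extract_context()]).
#' @param intronic_len,exonic_len window lengths.
#' @return Named character vector over event ids (`NA` where out of bounds).
#' @export
extract_contexts <- function(events, genome, intronic_len = 20L,
                             exonic_len = 3L) {
  out <- vapply(seq_len(nrow(events)), function(i)
    extract_context(events[i, , drop = FALSE], genome, intronic_len,
                    exonic_len), character(1))
  stats::setNames(out, events$event_id)
}

#' Position frequency matrix and information content
#'
#' Per-position empirical base frequencies over a set of equal-length
#' context sequences, with information content
#' \eqn{IC = 2 - H} bits where \eqn{H} is the Shannon entropy (no
#' small-sample correction).
#'
#' @param contexts character vector of equal-length sequences over ACGT.
#' @param intronic_len intronic window length, used to label positions
#'   (exon first base = 0, intronic negative).
#' @return List of class `PositionFrequencyMatrix`: `freq` (4 x L matrix,
#'   rows A,C,G,T), `info_content` (bits per position), `positions`,
#'   `n_sequences`.
#' @export
build_pfm <- function(contexts, intronic_len = 20L) {
  contexts <- contexts[!is.na(contexts)]
  if (length(contexts) < 1) .stopf("need >= 1 sequence")
  lens <- nchar(contexts)
  if (length(unique(lens)) != 1) .stopf("ragged sequence lengths")
  L <- lens[1]
  mat <- do.call(rbind, strsplit(contexts, ""))
  bases <- c("A", "C", "G", "T")
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = bases))
    as.numeric(tab) / length(contexts)
  }, numeric(4))
  rownames(freq) <- bases
  positions <- seq_len(L) - intronic_len - 1L
  colnames(freq) <- positions
  h <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  structure(list(freq = freq, info_content = 2 - h, positions = positions,
                 n_sequences = length(contexts)),
            class = "PositionFrequencyMatrix")
}

#' Base enrichment at one acceptor position
#'
#' Two-sided Fisher's exact test of the 2x2 table (base vs not-base) x
#' (dysregulated vs control) at the given position. The odds ratio is the
#' sample cross-product ratio, with a Haldane correction (+0.5 to every
#' cell) when any cell is zero.
#'
#' @param set_dys,set_ctrl character vectors of equal-length contexts.
#' @param position position index (exon first base = 0; the canonical
#'   query is -3).
#' @param base single base (default `"T"`).
#' @param intronic_len intronic window length (position labelling).
#' @return List with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
position_enrichment_test <- function(set_dys, set_ctrl, position = -3L,
                                     base = "T", intronic_len = 20L) {
  set_dys <- set_dys[!is.na(set_dys)]; set_ctrl <- set_ctrl[!is.na(set_ctrl)]
  if (length(set_dys) < 1 || length(set_ctrl) < 1)
    .stopf("both context sets must be non-empty")
  j <- position + intronic_len + 1L
  if (j < 1 || j > nchar(set_dys[1])) .stopf("position outside window")
  hit_d <- substr(set_dys, j, j) == base
  hit_c <- substr(set_ctrl, j, j) == base
  a <- sum(hit_d); b <- sum(!hit_d); cc <- sum(hit_c); d <- sum(!hit_c)
  tab <- matrix(c(a, b, cc, d), 2, 2,
                dimnames = list(c("base", "other"), c("dys", "ctrl")))
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Select dysregulated and control context sets from comparison results
#'
#' Dysregulated events pass the calling thresholds (strict); control
#' events are unperturbed: FDR > `ctrl_fdr_min` and, under the default
#' `control = "unperturbed"` rule, |dPSI| < `ctrl_max_abs_dpsi` (0.1%).
#' `control = "changed-but-nonsig"` instead requires |dPSI| >
#' `ctrl_max_abs_dpsi` with FDR > `ctrl_fdr_min` (a published-methods
#' variant retained for comparison; see the methods vignette). The two
#' sets are disjoint by construction.
#'
#' @param results a `ComparisonResult` data.frame.
#' @param fdr_max,min_abs_dpsi dysregulation thresholds.
#' @param ctrl_fdr_min,ctrl_max_abs_dpsi control thresholds.
#' @param control control-definition rule (see above).
#' @return List with character id vectors `dysregulated` and `control`.
#' @export
select_context_sets <- function(results, fdr_max = 0.05,
                                min_abs_dpsi = 0.10,
                                ctrl_fdr_min = 0.50,
                                ctrl_max_abs_dpsi = 0.001,
                                control = c("unperturbed",
                                            "changed-but-nonsig")) {
  control <- match.arg(control)
  ok <- !is.na(results$fdr) & !is.na(results$delta_psi)
  dys <- ok & results$fdr < fdr_max & abs(results$delta_psi) > min_abs_dpsi
  ctrl <- if (control == "unperturbed")
    ok & results$fdr > ctrl_fdr_min & abs(results$delta_psi) < ctrl_max_abs_dpsi
  else
    ok & results$fdr > ctrl_fdr_min & abs(results$delta_psi) > ctrl_max_abs_dpsi
  ctrl <- ctrl & !dys
  if (!any(ctrl)) warning("empty control set at these thresholds")
  list(dysregulated = results$event_id[dys],
       control = results$event_id[ctrl])
}
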
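# Fixtures built in code: a factorial table with exact replicate counts per
# condition, a sampled table around given condition PSI, and a toy genome
# with planted acceptor contexts.

# table whose replicates are identical within each condition; counts chosen
# so that per-replicate PSI is exact
make_exact_table <- function(inc_by_cond, skip_by_cond, reps = 5,
                             event_type = "SE", inc_norm = 1L) {
  ne <- length(inc_by_cond[[1]])
  events <- data.frame(
    event_id = sprintf("E%03d", seq_len(ne)),
    gene_id = sprintf("G%03d", seq_len(ne)),
    event_type = rep_len(event_type, ne),
    chrom = "chrT", strand = "+",
    coord1 = 100, coord2 = 300, coord3 = 420, coord4 = 700,
    inc_junction_count = inc_norm, skip_junction_count = 1L,
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0(rep(c("WV", "WD", "MV", "MD"), each = reps), seq_len(reps)),
    genotype = rep(c("WT", "WT", "MT", "MT"), each = reps),
    treatment = rep(c("Veh", "Drug", "Veh", "Drug"), each = reps),
    stringsAsFactors = FALSE)
  cond <- paste(samples$genotype, samples$treatment, sep = ".")
  inc <- sapply(cond, function(cc) inc_by_cond[[cc]])
  skp <- sapply(cond, function(cc) skip_by_cond[[cc]])
  junction_count_table(events, samples, matrix(inc, ne), matrix(skp, ne))
}

# table sampled from beta-binomial noise around condition-level true PSI
make_sampled_table <- function(psi_by_cond, reps = 5, total_mean = 60,
                               rho = 0.05, event_type = "SE", seed = 1) {
  set.seed(seed)
  ne <- nrow(psi_by_cond)
  samples <- data.frame(
    sample_id = paste0(rep(c("WV", "WD", "MV", "MD"), each = reps), seq_len(reps)),
    genotype = rep(c("WT", "WT", "MT", "MT"), each = reps),
    treatment = rep(c("Veh", "Drug", "Veh", "Drug"), each = reps),
    stringsAsFactors = FALSE)
  cond <- paste(samples$genotype, samples$treatment, sep = ".")
  inc <- skp <- matrix(0L, ne, length(cond))
  for (j in seq_along(cond)) {
    tot <- stats::rnbinom(ne, mu = total_mean, size = 10)
    cts <- sample_event_counts(psi_by_cond[, cond[j]], tot, rho)
    inc[, j] <- cts$inclusion; skp[, j] <- cts$skipping
  }
  events <- data.frame(
    event_id = sprintf("E%04d", seq_len(ne)),
    gene_id = sprintf("G%04d", seq_len(ne)),
    event_type = rep_len(event_type, ne),
    chrom = "chrT", strand = "+",
    coord1 = 100, coord2 = 300, coord3 = 420, coord4 = 700,
    inc_junction_count = 1L, skip_junction_count = 1L,
    stringsAsFactors = FALSE)
  junction_count_table(events, samples, inc, skp)
}

# condition-PSI matrix for an all-null design
null_psi <- function(ne, psi = 0.5) {
  m <- matrix(psi, ne, 4)
  colnames(m) <- condition_levels()
  m
}

# plant acceptor contexts into a toy genome so extract_context can recover
# them; events get non-overlapping 200-bp slots
plant_genome <- function(contexts, strand, event_type = "SE",
                         intronic_len = 20L, exonic_len = 3L) {
  ne <- length(contexts)
  slot <- (seq_len(ne) - 1L) * 200L
  chrom_len <- ne * 200L + 200L
  g <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  events <- data.frame(
    event_id = sprintf("E%03d", seq_len(ne)),
    event_type = rep_len(event_type, ne), chrom = "chrT",
    coord1 = NA_integer_, coord2 = NA_integer_,
    coord3 = NA_integer_, coord4 = NA_integer_,
    strand = strand, stringsAsFactors = FALSE)
  for (i in seq_len(ne)) {
    ctx <- strsplit(contexts[i], "")[[1]]
    if (events$event_type[i] == "SE") {
      cas_start <- slot[i] + 100L; cas_end <- slot[i] + 140L
      events$coord1[i] <- slot[i] + 20L; events$coord2[i] <- cas_start
      events$coord3[i] <- cas_end; events$coord4[i] <- slot[i] + 180L
      if (strand[i] == "+") {
        g[(cas_start - intronic_len + 1L):(cas_start + exonic_len)] <- ctx
      } else {
        rc <- rev(chartr("ACGT", "TGCA", ctx))
        g[(cas_end - exonic_len + 1L):(cas_end + intronic_len)] <- rc
      }
    } else {
      int_start <- slot[i] + 60L; int_end <- slot[i] + 150L
      events$coord1[i] <- int_start; events$coord2[i] <- int_end
      if (strand[i] == "+") {
        g[(int_end - intronic_len + 1L):(int_end + exonic_len)] <- ctx
      } else {
        rc <- rev(chartr("ACGT", "TGCA", ctx))
        g[(int_start - exonic_len + 1L):(int_start + intronic_len)] <- rc
      }
    }
  }
  list(events = events, genome = c(chrT = paste(g, collapse = "")))
}
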
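# Independent brute-force oracles, deliberately naive and separate from the
# package's dynamic-programming / Biostrings code paths.

# All nested secondary structures of a sequence, by direct recursion over
# "first position unpaired or paired with every legal k".  Returns a list
# of partner vectors (0 = unpaired, 1-based partners).
oracle_enumerate_structures <- function(sequence, min_loop = 3L) {
  bases <- strsplit(toupper(chartr("T", "U", sequence)), "")[[1]]
  can_pair <- function(a, b) {
    p <- paste0(a, b)
    p %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  }
  n <- length(bases)
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    out <- list()
    for (s in rec(i + 1L, j)) out[[length(out) + 1L]] <- s
    if (j - i >= min_loop + 1L) {
      for (k in (i + min_loop + 1L):j) {
        if (!can_pair(bases[i], bases[k])) next
        for (s1 in rec(i + 1L, k - 1L)) {
          for (s2 in rec(k + 1L, j)) {
            out[[length(out) + 1L]] <- c(list(c(i, k)), s1, s2)
          }
        }
      }
    }
    out
  }
  lapply(rec(1L, n), function(pairs) {
    partner <- integer(n)
    for (pr in pairs) {
      partner[pr[1]] <- pr[2]
      partner[pr[2]] <- pr[1]
    }
    partner
  })
}

# direct pair-score sum for a partner vector
oracle_structure_energy <- function(partner, sequence,
                                    scores = c(GC = -3, CG = -3, AU = -2,
                                               UA = -2, GU = -1, UG = -1)) {
  bases <- strsplit(toupper(chartr("T", "U", sequence)), "")[[1]]
  i <- which(partner > seq_along(partner))
  if (length(i) == 0L) return(0)
  sum(scores[paste0(bases[i], bases[partner[i]])])
}

# sliding-window Hamming search for a site in a transcript (0-based starts)
oracle_hamming_hits <- function(site, transcript, max_mm) {
  site <- strsplit(chartr("U", "T", toupper(site)), "")[[1]]
  tx <- strsplit(chartr("U", "T", toupper(transcript)), "")[[1]]
  L <- length(site)
  hits <- integer(0)
  if (length(tx) < L) return(hits)
  for (s in 0:(length(tx) - L)) {
    mm <- sum(tx[(s + 1):(s + L)] != site)
    if (mm <= max_mm) hits <- c(hits, s)
  }
  hits
}

# brute-force count of admissible gapmer tuples (wl, gap, wr, offset)
oracle_gapmer_count <- function(n, junction, length_range, gap_range, wing_range) {
  count <- 0L
  for (L in length_range[1]:length_range[2]) {
    for (g in gap_range[1]:gap_range[2]) {
      for (wl in wing_range[1]:wing_range[2]) {
        wr <- L - g - wl
        if (wr < wing_range[1] || wr > wing_range[2]) next
        for (s in 0:(n - L)) {
          if (s + L > n) next
          gap_lo <- s + wr
          gap_hi <- s + wr + g
          if (gap_lo < junction && gap_hi > junction) count <- count + 1L
        }
      }
    }
  }
  count
}

# canonical string form of a structure set, for set comparison
structure_set_key <- function(partners) {
  sort(vapply(partners, paste, character(1), collapse = ","))
}

# random sequence helper
random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# the small exhaustively-foldable locus used across design tests
oracle_locus <- function() {
  generate_synthetic_locus(synthetic_locus_spec(
    exon15_length = 8L, exon16_length = 8L, exon17_length = 6L,
    occlusion_span = c(3L, 8L), spacer = 3L))
}

# accessibility profiles and differential map for a locus, exhaustive mode
locus_pipeline <- function(loc) {
  ewt <- fold_ensemble(loc$pair$wt_sequence)
  emut <- fold_ensemble(loc$pair$mut_sequence)
  pw <- compute_ss_count(ewt, allele = "wt")
  pm <- compute_ss_count(emut, allele = "mut")
  list(profile_wt = pw, profile_mut = pm,
       diff = differential_accessibility(classify_accessibility(pm),
                                         classify_accessibility(pw), loc$pair))
}
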
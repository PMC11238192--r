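#' Constraints for gapmer enumeration and mixmer conversion
#'
#' Defaults follow the screened design space: total lengths 13-23 nt,
#' central PS-DNA gaps of 7-11 nt, RNA wings of 3-7 nt, and a minimum of
#' 4 consecutive PS-DNA residues for RNase-H competence after mixmer
#' conversion.
#'
#' @param length_range,gap_range,wing_range Inclusive nt intervals
#'   `c(min, max)`.
#' @param wing_chemistry Sugar for gapmer wings: "OMe2", "MOE2" or "LNA".
#' @param rna_block_chemistry Sugar for mixmer RNA blocks.
#' @param min_dna_run Minimum PS-DNA run a converted mixmer must keep.
#' @param min_block Minimum RNA block size after coalescing.
#' @param junction_cover Require the DNA gap to straddle the junction.
#' @return List of class `design_constraints`.
#' @export
design_constraints <- function(length_range = c(13L, 23L),
                               gap_range = c(7L, 11L),
                               wing_range = c(3L, 7L),
                               wing_chemistry = c("OMe2", "MOE2", "LNA"),
                               rna_block_chemistry = "OMe2",
                               min_dna_run = 4L,
                               min_block = 2L,
                               junction_cover = TRUE) {
  wing_chemistry <- match.arg(wing_chemistry)
  stopifnot(rna_block_chemistry %in% c("OMe2", "MOE2", "LNA"),
            length_range[1] <= length_range[2],
            gap_range[1] <= gap_range[2], wing_range[1] <= wing_range[2],
            min_dna_run >= 1L, min_block >= 1L)
  structure(list(length_range = as.integer(length_range),
                 gap_range = as.integer(gap_range),
                 wing_range = as.integer(wing_range),
                 wing_chemistry = wing_chemistry,
                 rna_block_chemistry = rna_block_chemistry,
                 min_dna_run = as.integer(min_dna_run),
                 min_block = as.integer(min_block),
                 junction_cover = isTRUE(junction_cover)),
            class = "design_constraints")
}

# target position (0-based, mutant coords) opposite ASO position p (1-based)
aso_pos_to_target <- function(design, p) {
  fp <- design$footprint
  fp[1] + (fp[2] - fp[1]) - p
}

#' Enumerate junction-straddling gapmer candidates
#'
#' Emits every (left wing, gap, right wing, footprint offset) combination
#' within the constraints whose PS-DNA gap straddles the mutant junction
#' (at least one gap base on each side). Each design is the reverse
#' complement of its mutant footprint, wings in the wing chemistry, gap in
#' PS-DNA, ordered deterministically by (length, gap, footprint offset,
#' left wing).
#'
#' @param pair A [build_junction_pair()] result.
#' @param constraints A [design_constraints()] object.
#' @return List of `oligo_design`s (possibly empty), each carrying its
#'   0-based half-open mutant `footprint`.
#' @export
enumerate_gapmers <- function(pair, constraints = design_constraints()) {
  stopifnot(inherits(pair, "transcript_pair"),
            inherits(constraints, "design_constraints"))
  n <- nchar(pair$mut_sequence)
  j <- pair$mut_junction
  target <- pair$mut_sequence
  out <- list()
  for (L in constraints$length_range[1]:constraints$length_range[2]) {
    for (g in constraints$gap_range[1]:constraints$gap_range[2]) {
      for (s in 0:max(0L, n - L)) {
        for (wl in constraints$wing_range[1]:constraints$wing_range[2]) {
          wr <- L - g - wl
          if (wr < constraints$wing_range[1] || wr > constraints$wing_range[2]) next
          if (s + L > n) next
          # ASO gap positions [wl+1, wl+g] face target interval [s+wr, s+wr+g)
          gap_lo <- s + wr
          gap_hi <- s + wr + g
          if (constraints$junction_cover && !(gap_lo < j && gap_hi > j)) next
          bases <- seq_chars(reverse_complement(substr(target, s + 1L, s + L)))
          sugar <- c(rep(constraints$wing_chemistry, wl), rep("DNA", g),
                     rep(constraints$wing_chemistry, wr))
          out[[length(out) + 1L]] <- oligo_design(
            name = sprintf("G_L%02d_g%02d_w%d.%d_s%03d", L, g, wl, wr, s),
            base = bases, sugar = sugar, category = "gapmer",
            footprint = c(s, s + L))
        }
      }
    }
  }
  out
}

#' Convert a gapmer to an accessibility-guided mixmer
#'
#' Re-assigns the design's chemistry from the differential accessibility
#' map: ASO positions complementary to mutant-open/wild-type-closed
#' target positions become RNA (the constraint's block chemistry),
#' everything else PS-DNA. Singleton RNA assignments are extended to
#' blocks of at least `min_block` toward the more accessible neighbor
#' (larger mutant-minus-wild-type ss-fraction margin). If no DNA run of
#' `min_dna_run` survives, RNA assignments are revoked most-3'-first
#' until one does. An empty differential map returns the design unchanged
#' with attribute `warning = "empty differential map"`.
#'
#' The assignment is a pure function of (footprint, differential map,
#' constraints), so re-applying it is a no-op.
#'
#' @param design An `oligo_design` with a known mutant footprint.
#' @param diff A [differential_accessibility()] result.
#' @param pair The `transcript_pair`.
#' @param constraints A [design_constraints()] object.
#' @return A new `oligo_design` (category re-inferred; name suffixed
#'   `.mix`).
#' @export
place_mixmer_chemistry <- function(design, diff, pair,
                                   constraints = design_constraints()) {
  stopifnot(inherits(design, "oligo_design"), inherits(diff, "differential_map"),
            inherits(pair, "transcript_pair"))
  if (is.null(design$footprint)) stop("design has no footprint", call. = FALSE)
  if (length(diff$mut_accessible_wt_closed) == 0L) {
    out <- design
    attr(out, "warning") <- "empty differential map"
    return(out)
  }
  L <- nrow(design$residues)
  targets <- vapply(seq_len(L), function(p) aso_pos_to_target(design, p), numeric(1))
  rna <- targets %in% diff$mut_accessible_wt_closed

  # coalesce singleton RNA assignments into blocks of >= min_block,
  # extending toward the neighbor with the larger accessibility margin
  margin_at <- function(q) {
    if (q < 1L || q > L || rna[q]) return(-Inf)
    m <- diff$margin[as.character(targets[q])]
    if (length(m) == 0L || is.na(m)) -Inf else unname(m)
  }
  if (constraints$min_block > 1L) {
    frozen <- integer(0)
    repeat {
      r <- rle(rna)
      stops <- cumsum(r$lengths)
      starts <- stops - r$lengths + 1L
      small <- which(r$values & r$lengths < constraints$min_block)
      small <- small[!(starts[small] %in% frozen)]
      if (length(small) == 0L) break
      k <- small[1L]
      left <- starts[k] - 1L; right <- stops[k] + 1L
      ml <- margin_at(left); mr <- margin_at(right)
      if (ml == -Inf && mr == -Inf) {
        frozen <- c(frozen, starts[k])  # boxed in; leave as is
      } else if (ml >= mr) {
        rna[left] <- TRUE
      } else {
        rna[right] <- TRUE
      }
    }
  }

  enforce <- function(rna) {
    r <- rle(!rna)  # DNA runs
    if (any(r$values & r$lengths >= constraints$min_dna_run)) return(rna)
    NULL
  }
  while (is.null(enforce(rna)) && any(rna)) {
    rna[max(which(rna))] <- FALSE  # revoke the most-3' RNA assignment
  }

  sugar <- ifelse(rna, constraints$rna_block_chemistry, "DNA")
  oligo_design(name = paste0(sub("\\.mix$", "", design$name), ".mix"),
               base = design$residues$base, sugar = sugar,
               mismatch_positions = design$mismatch_positions,
               footprint = design$footprint)
}

#' Generate single-mismatch variants of a design
#'
#' Candidate sites are the ASO positions complementary to target
#' positions that are open in both alleles within the named exon region
#' (typically the exon upstream of the skipped one). Each variant swaps
#' that single base for its Watson-Crick complement (A<->U/T, G<->C),
#' guaranteeing a non-pairing apposition on either allele while leaving
#' the chemistry pattern untouched.
#'
#' @param design Parent `oligo_design` (mixmer or gapmer) with footprint.
#' @param diff A [differential_accessibility()] result.
#' @param pair The `transcript_pair`.
#' @param region Exon id to which mismatch sites are restricted.
#' @return List of `oligo_design`s (one per candidate; empty when there
#'   are no candidates), category `mismatch_mixmer`, `mismatch_positions`
#'   recording the 1-based ASO position.
#' @export
generate_mismatch_variants <- function(design, diff, pair, region) {
  stopifnot(inherits(design, "oligo_design"), inherits(diff, "differential_map"),
            inherits(pair, "transcript_pair"))
  if (is.null(design$footprint)) stop("design has no footprint", call. = FALSE)
  cand_t <- diff$open_in_both
  ex <- pair$exons_mut[pair$exons_mut$id == region, ]
  if (nrow(ex) != 1L) stop("exon '", region, "' not in the mutant transcript",
                           call. = FALSE)
  cand_t <- cand_t[cand_t >= ex$start & cand_t < ex$end]
  L <- nrow(design$residues)
  targets <- vapply(seq_len(L), function(p) aso_pos_to_target(design, p), numeric(1))
  cand_p <- which(targets %in% cand_t)
  out <- list()
  for (p in sort(cand_p)) {
    base <- design$residues$base
    swap <- complement_base(chartr("T", "U", base[p]))
    if (design$residues$sugar[p] == "DNA") swap <- chartr("U", "T", swap)
    base[p] <- swap
    out[[length(out) + 1L]] <- oligo_design(
      name = sprintf("%s.mm%02d", design$name, p),
      base = base, sugar = design$residues$sugar,
      category = "mismatch_mixmer",
      mismatch_positions = sort(unique(c(design$mismatch_positions, p))),
      footprint = design$footprint)
  }
  out
}

#' Accessibility-corrected binding annotation for both alleles
#'
#' The per-allele total score decomposes as `dG_total = dG_hybrid +
#' dG_open`. `dG_hybrid` sums, over complementary appositions, the pair
#' score of the baseline energy model plus a per-residue chemistry bonus
#' (modified riboses bind more strongly), and adds `mismatch_penalty` per
#' non-pairing apposition. `dG_open` charges each paired position the
#' magnitude of its binding score scaled by `w * (1 - ss_fraction)` of its
#' target position, so binding into structured (closed) regions is
#' penalized in proportion to the affinity demanded there; it is always
#' >= 0. On the mutant the alignment is the declared footprint; on the
#' wild type it is the best (lowest total) ungapped alignment over the
#' profiled window, which for a junction-spanning design necessarily
#' mismatches across one half.
#'
#' @param design An `oligo_design` with a mutant footprint.
#' @param pair The `transcript_pair`.
#' @param profile_mut,profile_wt [compute_ss_count()] profiles covering
#'   the mutant footprint and its wild-type image.
#' @param w Accessibility penalty weight (score units per fully closed
#'   position, default 1).
#' @param chem_bonus Additive score bonus per paired residue, by sugar.
#' @param mismatch_penalty Score added per mismatched apposition.
#' @param params [fold_params()] supplying the pair scores.
#' @return Object of class `affinity_annotation` with `dG_hybrid_*`,
#'   `dG_open_*`, `dG_total_*` per allele, `discrimination`
#'   (`dG_total_wt - dG_total_mut`; positive when the mutant is favored)
#'   and `wt_offset` (0-based start of the best wild-type alignment).
#' @export
annotate_affinity <- function(design, pair, profile_mut, profile_wt, w = 1,
                              chem_bonus = c(DNA = 0, OMe2 = -0.5,
                                             MOE2 = -1.0, LNA = -1.5),
                              mismatch_penalty = 1,
                              params = fold_params()) {
  stopifnot(inherits(design, "oligo_design"),
            inherits(profile_mut, "ss_count_profile"),
            inherits(profile_wt, "ss_count_profile"))
  if (is.null(design$footprint)) stop("design has no footprint", call. = FALSE)
  L <- nrow(design$residues)
  aso <- chartr("T", "U", design$residues$base)
  bonus <- chem_bonus[design$residues$sugar]
  S <- pair_score_matrix(c("A", "C", "G", "U"), params)
  idx <- c(A = 1L, C = 2L, G = 3L, U = 4L)

  score_alignment <- function(win_bases, win_fr, start0) {
    # ASO position p faces window index start0 + L - p (1-based window idx)
    hyb <- 0; open <- 0
    for (p in seq_len(L)) {
      iw <- start0 + L - p + 1L
      tb <- win_bases[iw]
      ps <- S[idx[[aso[p]]], idx[[tb]]]
      if (is.na(ps)) {
        hyb <- hyb + mismatch_penalty
      } else {
        sc <- ps + bonus[[p]]
        hyb <- hyb + sc
        open <- open + abs(sc) * w * (1 - win_fr[iw])
      }
    }
    c(hyb = hyb, open = open)
  }

  # mutant: fixed at the footprint
  fp <- design$footprint
  m_lo <- profile_mut$offset
  m_hi <- profile_mut$offset + nchar(profile_mut$sequence)
  if (fp[1] < m_lo || fp[2] > m_hi) {
    stop("design footprint lies outside the profiled mutant window", call. = FALSE)
  }
  mb <- seq_chars(profile_mut$sequence)
  mres <- score_alignment(mb, profile_mut$ss_fraction, fp[1] - m_lo)

  # wild type: best ungapped alignment over the profiled window
  wb <- seq_chars(profile_wt$sequence)
  nw <- length(wb)
  if (nw < L) stop("wild-type window shorter than the design", call. = FALSE)
  best <- NULL; best_off <- NA_integer_
  for (o in 0:(nw - L)) {
    r <- score_alignment(wb, profile_wt$ss_fraction, o)
    if (is.null(best) || sum(r) < sum(best) - 1e-12) {
      best <- r
      best_off <- o
    }
  }

  structure(list(
    dG_hybrid_mut = unname(mres["hyb"]), dG_open_mut = unname(mres["open"]),
    dG_total_mut = unname(sum(mres)),
    dG_hybrid_wt = unname(best["hyb"]), dG_open_wt = unname(best["open"]),
    dG_total_wt = unname(sum(best)),
    discrimination = unname(sum(best) - sum(mres)),
    wt_offset = profile_wt$offset + best_off
  ), class = "affinity_annotation")
}

#' Predicted allele selectivity at a working dose
#'
#' Maps the per-allele total binding scores to dissociation constants on a
#' nanomolar scale, `Kd = exp((dG_total - dG_ref) / kT)`, and reports the
#' ratio of predicted fractional target engagement, `theta =
#' dose / (dose + Kd)`, between the mutant and wild-type alleles:
#' `selectivity = (dose + Kd_wt) / (dose + Kd_mut)`. Because engagement
#' saturates, a mutant allele bound far above its Kd tolerates an affinity
#' loss (e.g. a deliberate mismatch) that sharply de-represses the
#' wild-type allele -- the mechanism by which a mismatch raises functional
#' selectivity even though it lowers both raw affinities equally.
#'
#' @param annotation An [annotate_affinity()] result.
#' @param dose_nM Working concentration (default 100 nM, the screening
#'   dose).
#' @param dG_ref Score giving Kd = 1 nM (calibration constant of the
#'   score-unit scale).
#' @param kT Score units per e-fold of Kd.
#' @return List with `kd_mut`, `kd_wt` (nM) and `selectivity`
#'   (mutant-over-wild-type engagement ratio; > 1 when the mutant is
#'   preferentially engaged).
#' @export
predict_selectivity <- function(annotation, dose_nM = 100, dG_ref = -25, kT = 2) {
  stopifnot(inherits(annotation, "affinity_annotation"), dose_nM > 0, kT > 0)
  kd_mut <- exp((annotation$dG_total_mut - dG_ref) / kT)
  kd_wt <- exp((annotation$dG_total_wt - dG_ref) / kT)
  list(kd_mut = kd_mut, kd_wt = kd_wt,
       selectivity = (dose_nM + kd_wt) / (dose_nM + kd_mut))
}

#' Rank annotated designs
#'
#' Stable sort by: no off-target hits first, then discrimination
#' (descending), then mutant total binding score (ascending, i.e. most
#' favorable first), then name.
#'
#' @param designs List of `oligo_design`s.
#' @param annotations Parallel list of [annotate_affinity()] results.
#' @param off_target_hits Integer vector of hit counts (default all 0).
#' @param path Optional TSV output path.
#' @return data.frame, one row per design in rank order, with columns
#'   `rank`, `name`, `category`, `length`, `gc_percent`, `tm_celsius`,
#'   `longest_dna_run`, `off_target_hits`, `dG_total_mut`, `dG_total_wt`,
#'   `discrimination`, `notation`.
#' @export
rank_designs <- function(designs, annotations,
                         off_target_hits = rep(0L, length(designs)),
                         path = NULL) {
  stopifnot(length(designs) == length(annotations),
            length(off_target_hits) == length(designs))
  df <- data.frame(
    name = vapply(designs, `[[`, character(1), "name"),
    category = vapply(designs, `[[`, character(1), "category"),
    length = vapply(designs, function(d) nrow(d$residues), integer(1)),
    gc_percent = vapply(designs, gc_content, numeric(1)),
    tm_celsius = round(vapply(designs, melting_temperature, numeric(1)), 1),
    longest_dna_run = vapply(designs, function(d) dna_run_profile(d)$longest,
                             integer(1)),
    off_target_hits = as.integer(off_target_hits),
    dG_total_mut = vapply(annotations, `[[`, numeric(1), "dG_total_mut"),
    dG_total_wt = vapply(annotations, `[[`, numeric(1), "dG_total_wt"),
    discrimination = vapply(annotations, `[[`, numeric(1), "discrimination"),
    notation = vapply(designs, serialize_oligo, character(1)),
    stringsAsFactors = FALSE)
  ord <- order(df$off_target_hits > 0L, -df$discrimination, df$dG_total_mut,
               df$name, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
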
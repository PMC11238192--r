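test_that("gapmer enumeration straddles the junction and matches the tuple oracle", {
  loc <- oracle_locus()
  pair <- loc$pair
  cons <- design_constraints(length_range = c(13, 14), gap_range = c(7, 8),
                             wing_range = c(3, 4))
  g <- enumerate_gapmers(pair, cons)
  expect_gt(length(g), 0L)
  j <- pair$mut_junction
  mut <- pair$mut_sequence
  for (d in g) {
    L <- nrow(d$residues)
    wl <- sum(cumprod(d$residues$sugar != "DNA"))
    gl <- dna_run_profile(d)$runs
    expect_length(gl, 1L)
    wr <- L - wl - gl
    fp <- d$footprint
    gap_lo <- fp[1] + wr
    gap_hi <- fp[1] + wr + gl
    expect_true(gap_lo < j && gap_hi > j, label = d$name)
    # perfect reverse complement of the mutant footprint
    expect_identical(chartr("T", "U", paste(d$residues$base, collapse = "")),
                     reverse_complement(substr(mut, fp[1] + 1, fp[2])))
  }
  expect_equal(length(g),
               oracle_gapmer_count(nchar(mut), j, cons$length_range,
                                   cons$gap_range, cons$wing_range))
  # deterministic order: re-enumeration is identical
  expect_identical(vapply(g, `[[`, character(1), "name"),
                   vapply(enumerate_gapmers(pair, cons), `[[`, character(1), "name"))
  # constraints that cannot straddle the junction: empty list, no error
  tight <- design_constraints(length_range = c(13, 13), gap_range = c(7, 7),
                              wing_range = c(3, 3))
  small_pair <- build_junction_pair(list(exon("a", "AAAA"), exon("b", "CCC"),
                                         exon("c", "GGGG")), skip_index = 2)
  expect_length(enumerate_gapmers(small_pair, tight), 0L)
})

test_that("mixmer placement tracks the differential map and keeps a DNA gap", {
  loc <- oracle_locus()
  pl <- locus_pipeline(loc)
  cons <- design_constraints(length_range = c(13, 13), gap_range = c(7, 7),
                             wing_range = c(3, 3))
  g <- enumerate_gapmers(loc$pair, cons)
  d <- g[[2]]
  m <- place_mixmer_chemistry(d, pl$diff, loc$pair, cons)
  # RNA blocks sit exactly opposite the differential (occluded) positions,
  # after coalescing; here the occlusion is a contiguous 5-nt block
  L <- nrow(m$residues)
  targets <- d$footprint[1] + L - seq_len(L)
  expect_setequal(targets[m$residues$sugar != "DNA"],
                  intersect(pl$diff$mut_accessible_wt_closed,
                            d$footprint[1]:(d$footprint[2] - 1L)))
  expect_equal(m$category, "mixmer")
  runs <- dna_run_profile(m)$runs
  expect_gte(length(runs), 2L)
  expect_gte(max(runs), cons$min_dna_run)
  # idempotence
  m2 <- place_mixmer_chemistry(m, pl$diff, loc$pair, cons)
  expect_identical(m2$residues, m$residues)
  # empty differential map: unchanged, warned
  empty <- pl$diff
  empty$mut_accessible_wt_closed <- integer(0)
  u <- place_mixmer_chemistry(d, empty, loc$pair, cons)
  expect_identical(u$residues, d$residues)
  expect_equal(attr(u, "warning"), "empty differential map")
})

test_that("singleton RNA assignments are coalesced into blocks", {
  loc <- oracle_locus()
  pl <- locus_pipeline(loc)
  cons <- design_constraints(length_range = c(13, 13), gap_range = c(7, 7),
                             wing_range = c(3, 3), min_block = 2)
  d <- enumerate_gapmers(loc$pair, cons)[[2]]
  # force a singleton differential position
  solo <- pl$diff
  solo$mut_accessible_wt_closed <- solo$mut_accessible_wt_closed[3]
  m <- place_mixmer_chemistry(d, solo, loc$pair, cons)
  r <- rle(m$residues$sugar != "DNA")
  expect_true(all(r$lengths[r$values] >= 2L))
})

test_that("mismatch variants are single complement swaps at open-in-both sites", {
  loc <- oracle_locus()
  pl <- locus_pipeline(loc)
  cons <- design_constraints(length_range = c(13, 13), gap_range = c(7, 7),
                             wing_range = c(3, 3))
  d <- enumerate_gapmers(loc$pair, cons)[[2]]
  m <- place_mixmer_chemistry(d, pl$diff, loc$pair, cons)
  vars <- generate_mismatch_variants(m, pl$diff, loc$pair, region = "exon15")
  expect_gt(length(vars), 0L)
  comp <- c(A = "U", U = "A", G = "C", C = "G", T = "A")
  for (v in vars) {
    ndiff <- sum(v$residues$base != m$residues$base)
    expect_equal(ndiff, 1L)
    p <- v$mismatch_positions
    expect_length(p, 1L)
    old <- chartr("T", "U", m$residues$base[p])
    new <- chartr("T", "U", v$residues$base[p])
    expect_equal(new, unname(comp[old]))
    expect_identical(v$residues$sugar, m$residues$sugar)  # chemistry untouched
    expect_equal(v$category, "mismatch_mixmer")
  }
  # no candidates -> empty list
  none <- pl$diff
  none$open_in_both <- integer(0)
  expect_length(generate_mismatch_variants(m, none, loc$pair, "exon15"), 0L)
})

test_that("published mismatch rows are complement swaps of the parent mixmer", {
  t1 <- load_table1()
  ds <- attr(t1, "designs")
  m7 <- chartr("T", "U", ds[["M-7"]]$residues$base)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  mm_rows <- t1[t1$paper_category == "mismatch_mixmer", ]
  for (i in seq_len(nrow(mm_rows))) {
    v <- chartr("T", "U", ds[[mm_rows$name[i]]]$residues$base)
    dpos <- which(v != m7)
    expect_equal(dpos, mm_rows$mismatch_position[i], label = mm_rows$name[i])
    expect_equal(v[dpos], unname(comp[m7[dpos]]), label = mm_rows$name[i])
  }
})

test_that("affinity annotation penalizes mismatches and closed footprints", {
  loc <- oracle_locus()
  pl <- locus_pipeline(loc)
  cons <- design_constraints(length_range = c(13, 13), gap_range = c(7, 7),
                             wing_range = c(3, 3))
  d <- enumerate_gapmers(loc$pair, cons)[[2]]
  ann <- annotate_affinity(d, loc$pair, pl$profile_mut, pl$profile_wt)
  expect_gte(ann$dG_open_mut, 0)
  expect_gte(ann$dG_open_wt, 0)
  # junction-spanning design favors the mutant
  expect_gt(ann$discrimination, 0)
  # one internal mismatch strictly worsens the mutant-side total
  b <- d$residues$base
  b[7] <- "A"  # apposes target A; cannot pair
  dmm <- oligo_design("mm", b, d$residues$sugar, footprint = d$footprint)
  ann_mm <- annotate_affinity(dmm, loc$pair, pl$profile_mut, pl$profile_wt)
  expect_gt(ann_mm$dG_total_mut, ann$dG_total_mut)
  # fully open vs fully closed footprint: open binds strictly better
  mkprof <- function(fr, seqs) {
    structure(list(ss_count = as.integer(round(fr * 10)), n_structures = 10L,
                   ss_fraction = rep(fr, nchar(seqs)), sequence = seqs,
                   offset = 0L, allele = NA_character_),
              class = "ss_count_profile")
  }
  mut <- loc$pair$mut_sequence
  open_prof <- mkprof(1, mut)
  closed_prof <- mkprof(0, mut)
  a_open <- annotate_affinity(d, loc$pair, open_prof, open_prof)
  a_closed <- annotate_affinity(d, loc$pair, closed_prof, closed_prof)
  expect_lt(a_open$dG_total_mut, a_closed$dG_total_mut)
  # footprint outside the profiled window errors
  short <- mkprof(1, substr(mut, 1, 5))
  expect_error(annotate_affinity(d, loc$pair, short, open_prof), "outside")
})

test_that("ranking is stable, off-target-aware and order-invariant", {
  loc <- oracle_locus()
  pl <- locus_pipeline(loc)
  cons <- design_constraints(length_range = c(13, 13), gap_range = c(7, 7),
                             wing_range = c(3, 3))
  g <- enumerate_gapmers(loc$pair, cons)
  anns <- lapply(g, annotate_affinity, pair = loc$pair,
                 profile_mut = pl$profile_mut, profile_wt = pl$profile_wt)
  r1 <- rank_designs(g[1], anns[1])
  expect_equal(r1$rank, 1L)
  # identical designs, one with off-target hits: clean one first
  r2 <- rank_designs(list(g[[1]], g[[1]]), list(anns[[1]], anns[[1]]),
                     off_target_hits = c(3L, 0L))
  expect_equal(r2$off_target_hits, c(0L, 3L))
  # permutation invariance of the ranked order
  ord <- rev(seq_along(g))
  ra <- rank_designs(g, anns)
  rb <- rank_designs(g[ord], anns[ord])
  expect_identical(ra$name, rb$name)
})

test_that("full pipeline ordering: gapmer < mixmer < mismatch-mixmer selectivity", {
  loc <- oracle_locus()
  pl <- locus_pipeline(loc)
  cons <- design_constraints(length_range = c(13, 13), gap_range = c(7, 7),
                             wing_range = c(3, 3))
  g <- enumerate_gapmers(loc$pair, cons)
  sel <- function(d) {
    predict_selectivity(annotate_affinity(d, loc$pair, pl$profile_mut,
                                          pl$profile_wt))$selectivity
  }
  best_g <- g[[which.max(vapply(g, sel, numeric(1)))]]
  m <- place_mixmer_chemistry(best_g, pl$diff, loc$pair, cons)
  vars <- generate_mismatch_variants(m, pl$diff, loc$pair, region = "exon15")
  expect_gte(length(vars), 1L)
  s_g <- sel(best_g)
  s_m <- sel(m)
  s_v <- max(vapply(vars, sel, numeric(1)))
  expect_gt(s_m, s_g)
  expect_gt(s_v, s_m)
})
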
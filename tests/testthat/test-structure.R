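test_that("folding degenerate and stem-loop sequences gives the expected optima", {
  e <- fold_ensemble("AAAA")
  expect_equal(e$n_structures, 1L)
  expect_true(all(e$structures[[1]]$partner == 0L))

  e2 <- fold_ensemble("GGGAAAACCC")
  opt <- e2$structures[[1]]
  expect_equal(opt$energy, -9)  # three G.C pairs across the AAAA loop
  expect_equal(format_dotbracket(opt$partner), "(((....)))")

  expect_error(fold_ensemble("ACGX"), "invalid nucleotide")
})

test_that("every returned structure satisfies the structure invariants", {
  set.seed(21)
  for (rep in 1:8) {
    s <- random_rna(sample(6:20, 1))
    e <- fold_ensemble(s)
    for (st in e$structures) {
      expect_silent(asodesign:::validate_structure(st$partner, s))
    }
  }
})

test_that("exhaustive folding matches the brute-force enumeration oracle", {
  set.seed(99)
  params <- fold_params()
  for (rep in 1:12) {
    s <- random_rna(sample(5:15, 1))
    e <- fold_ensemble(s, params)
    all_structs <- oracle_enumerate_structures(s, params$min_loop)
    energies <- vapply(all_structs, oracle_structure_energy, numeric(1), s)
    keep <- energies <= min(energies) + params$epsilon + 1e-9
    expect_identical(
      structure_set_key(lapply(e$structures, `[[`, "partner")),
      structure_set_key(all_structs[keep]),
      label = paste("sequence", s))
  }
})

test_that("sampled ensembles are seeded, sized and include the optimum", {
  s <- paste(rep("GGGAAAACCCAAA", 3), collapse = "")  # 39 nt > cutoff
  p <- fold_params(n_samples = 12, seed = 7)
  e1 <- fold_ensemble(s, p)
  e2 <- fold_ensemble(s, p)
  expect_equal(e1$n_structures, 12L)
  expect_equal(e1$mode, "sampled")
  expect_identical(lapply(e1$structures, `[[`, "partner"),
                   lapply(e2$structures, `[[`, "partner"))
  emin <- min(vapply(e1$structures, `[[`, numeric(1), "energy"))
  # the ensemble must contain a structure at the DP optimum energy
  opt_energy <- asodesign:::fold_dp_matrix(
    asodesign:::pair_score_matrix(strsplit(s, "")[[1]], p), p$min_loop)[1, nchar(s) + 1]
  expect_equal(emin, opt_energy)
})

test_that("ss-count equals a direct tally and conserves unpaired totals", {
  set.seed(31)
  for (rep in 1:6) {
    s <- random_rna(sample(8:16, 1))
    e <- fold_ensemble(s)
    prof <- compute_ss_count(e)
    tally <- Reduce(`+`, lapply(e$structures, function(st) as.integer(st$partner == 0L)))
    expect_identical(prof$ss_count, tally)
    expect_equal(sum(prof$ss_count),
                 sum(vapply(e$structures, function(st) sum(st$partner == 0L),
                            numeric(1))))
    expect_true(all(prof$ss_count >= 0 & prof$ss_count <= e$n_structures))
    expect_equal(prof$ss_fraction, prof$ss_count / e$n_structures)
  }
  # 3-structure toy ensemble, position unpaired in exactly 2
  s <- "GGGAAAACCC"
  structs <- list("(((....)))", "((......))", "..........")
  files <- vapply(structs, function(db) {
    f <- tempfile(fileext = ".db")
    writeLines(c(s, db), f)
    f
  }, character(1))
  ens <- import_ensemble(files, s)
  prof <- compute_ss_count(ens)
  expect_equal(prof$n_structures, 3L)
  expect_equal(prof$ss_count[3], 2L)       # paired in 1 of 3
  expect_equal(prof$ss_fraction[3], 2 / 3)
  expect_equal(prof$ss_count[5], 3L)       # loop position unpaired in all
})

test_that("accessibility classification is a monotone three-way partition", {
  mk <- function(fr) {
    structure(list(ss_count = round(fr * 30), n_structures = 30L,
                   ss_fraction = fr, sequence = strrep("A", length(fr)),
                   offset = 0L, allele = NA_character_),
              class = "ss_count_profile")
  }
  m <- classify_accessibility(mk(c(0, 0.5, 1, 1/3, 2/3)))
  expect_equal(m$class, c("closed", "semi_open", "open", "closed", "open"))
  expect_error(classify_accessibility(mk(0.5), t_open = 0.2, t_closed = 0.6),
               "t_closed < t_open")
  # monotone: higher fraction never moves a position toward closed
  rank <- c(closed = 1, semi_open = 2, open = 3)
  fr <- seq(0, 1, by = 0.05)
  cls <- classify_accessibility(mk(fr))$class
  expect_true(all(diff(rank[cls]) >= 0))
})

test_that("dot-bracket and CT readers parse, validate and round-trip", {
  partner <- parse_dotbracket("((((...))))")
  pairs0 <- cbind(which(partner > seq_along(partner)) - 1L,
                  partner[partner > seq_along(partner)] - 1L)
  expect_equal(pairs0, cbind(0:3, c(10L, 9L, 8L, 7L)))
  expect_identical(format_dotbracket(partner), "((((...))))")
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())"), "unbalanced")

  # CT write/read round trip
  s <- "GGGAAAACCC"
  p <- parse_dotbracket("(((....)))")
  ct <- tempfile(fileext = ".ct")
  n <- nchar(s)
  b <- strsplit(s, "")[[1]]
  writeLines(c(sprintf("%d dG = -9.0 toy", n),
               sprintf("%d %s %d %d %d %d", 1:n, b, 0:(n - 1), c(2:n, 0), p, 1:n)),
             ct)
  got <- read_ct(ct)
  expect_identical(got$partner, p)
  expect_equal(got$energy, -9)
  expect_identical(got$sequence, s)

  # inconsistent partner column
  bad <- tempfile(fileext = ".ct")
  lines <- readLines(ct)
  lines[2] <- "1 G 0 2 9 1"  # 1 says 9 but 9 says 2
  writeLines(lines, bad)
  expect_error(read_ct(bad), "inconsistent")

  # import: sequence mismatch names the first differing position
  db <- tempfile(fileext = ".db")
  writeLines(c("GGGAAAACCC", "(((....)))"), db)
  expect_error(import_ensemble(db, "GGGAAAACCG"), "position 10")
  ens <- import_ensemble(c(ct, db, db), s)
  expect_equal(ens$n_structures, 3L)
  expect_equal(ens$source, "imported")
})

test_that("differential map is empty for identical profiles and respects regions", {
  loc <- oracle_locus()
  pl <- locus_pipeline(loc)
  # identical profiles on both alleles: no differential positions
  same <- differential_accessibility(classify_accessibility(pl$profile_mut),
                                     classify_accessibility(pl$profile_mut),
                                     loc$pair)
  expect_length(same$mut_accessible_wt_closed, 0L)
  # the real differential: disjoint sets, all mappable
  d <- pl$diff
  expect_length(intersect(d$mut_accessible_wt_closed, d$open_in_both), 0L)
  expect_silent(map_mut_to_wt(loc$pair, d$mut_accessible_wt_closed))
  # region restriction to exon15 excludes every exon17 position
  d15 <- differential_accessibility(classify_accessibility(pl$profile_mut),
                                    classify_accessibility(pl$profile_wt),
                                    loc$pair, region = "exon15")
  ex17 <- loc$pair$exons_mut[loc$pair$exons_mut$id == "exon17", ]
  expect_true(all(d15$open_in_both < ex17$start))
  expect_error(differential_accessibility(classify_accessibility(pl$profile_mut),
                                          classify_accessibility(pl$profile_wt),
                                          loc$pair, region = "exon16"),
               "not present")
})

test_that("heatmap table applies majority and tie consensus rules", {
  mk <- function(fr, seqs) {
    structure(list(ss_count = as.integer(round(fr * 6)), n_structures = 6L,
                   ss_fraction = fr, sequence = seqs, offset = 0L,
                   allele = NA_character_),
              class = "ss_count_profile")
  }
  s <- "ACGU"
  p_open <- mk(rep(1, 4), s)
  p_closed <- mk(rep(0, 4), s)
  one <- export_heatmap_table(list(w1 = p_open))
  expect_equal(one$consensus, rep("open", 4))
  maj <- export_heatmap_table(list(a = p_open, b = p_open, c = p_open,
                                   d = p_open, e = p_closed, f = p_closed))
  expect_equal(maj$consensus, rep("open", 4))           # 4 open vs 2 closed
  tie <- export_heatmap_table(list(a = p_open, b = p_open, c = p_open,
                                   d = p_closed, e = p_closed, f = p_closed))
  expect_equal(tie$consensus, rep("semi_open", 4))      # 3-3 tie
  # TSV export round trip
  out <- tempfile(fileext = ".tsv")
  export_heatmap_table(list(w1 = p_open), path = out)
  expect_equal(nrow(utils::read.delim(out)), 4L)
})
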
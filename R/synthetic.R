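#' Specification of the synthetic exon-skip locus
#'
#' A minimal three-exon stand-in for an exon-skipped disease locus: the
#' middle exon is skippable (54 nt by default, so the deletion is
#' in-frame) and contains the reverse complement of an `occlusion_span`
#' inside the upstream exon. In the wild-type transcript that span is
#' sequestered in a helix with the middle exon (closed); in the
#' exon-skipped mutant the helix partner is gone and the span is open --
#' the structural difference the mixmer design exploits. Outside the
#' engineered helix the sequence is an unstructured (pairing-inert)
#' background, so the occlusion is the only structural signal.
#'
#' @param exon15_length,exon16_length,exon17_length Exon lengths (nt).
#' @param occlusion_span 0-based half-open interval within exon 15 (in
#'   exon-15-local coordinates) that the middle exon occludes. Default:
#'   the last 10 nt of exon 15.
#' @param spacer Unpaired nucleotides at the start of the middle exon so
#'   the engineered helix satisfies the minimum hairpin loop.
#' @param seed Integer seed (recorded; the default construction is
#'   deterministic).
#' @return List of class `synthetic_locus_spec`.
#' @export
synthetic_locus_spec <- function(exon15_length = 60L, exon16_length = 54L,
                                 exon17_length = 60L,
                                 occlusion_span = c(exon15_length - 10L,
                                                    exon15_length),
                                 spacer = 3L, seed = 1L) {
  occlusion_span <- as.integer(occlusion_span)
  if (occlusion_span[1] < 0L || occlusion_span[2] > exon15_length ||
      occlusion_span[1] >= occlusion_span[2]) {
    stop("occlusion_span must be a non-empty interval inside exon 15",
         call. = FALSE)
  }
  k <- occlusion_span[2] - occlusion_span[1]
  if (spacer + k > exon16_length) {
    stop("middle exon too short for the spacer plus the occlusion complement",
         call. = FALSE)
  }
  structure(list(exon15_length = as.integer(exon15_length),
                 exon16_length = as.integer(exon16_length),
                 exon17_length = as.integer(exon17_length),
                 occlusion_span = occlusion_span,
                 spacer = as.integer(spacer),
                 seed = as.integer(seed)),
            class = "synthetic_locus_spec")
}

#' Generate the synthetic locus and its ground-truth differential map
#'
#' Builds the three exons, the wild-type and exon-skipped transcripts and
#' the novel junction. The occlusion span is a G-only block whose C-only
#' reverse complement sits in the middle exon behind a short unpaired
#' spacer; all remaining positions are adenines. Under the baseline
#' energy model this makes the engineered helix the only possible pairing:
#' the wild type folds with the occlusion span fully paired, the mutant
#' with it fully unpaired, and the intended differential positions are
#' known exactly.
#'
#' @param spec A [synthetic_locus_spec()].
#' @return List with `pair` (a `transcript_pair`),
#'   `ground_truth_differential` (0-based mutant coordinates of the
#'   occluded span -- the positions a correct accessibility pipeline must
#'   report as mutant-accessible/wild-type-closed), `occluded_wt`
#'   (the same span in wild-type coordinates) and `spec`.
#' @export
generate_synthetic_locus <- function(spec = synthetic_locus_spec()) {
  stopifnot(inherits(spec, "synthetic_locus_spec"))
  k <- spec$occlusion_span[2] - spec$occlusion_span[1]
  e15 <- rep("A", spec$exon15_length)
  e15[(spec$occlusion_span[1] + 1L):spec$occlusion_span[2]] <- "G"
  e16 <- rep("A", spec$exon16_length)
  e16[(spec$spacer + 1L):(spec$spacer + k)] <- "C"
  e17 <- rep("A", spec$exon17_length)
  pair <- build_junction_pair(list(
    exon("exon15", paste(e15, collapse = "")),
    exon("exon16", paste(e16, collapse = "")),
    exon("exon17", paste(e17, collapse = ""))
  ), skip_index = 2L)
  gt <- spec$occlusion_span[1]:(spec$occlusion_span[2] - 1L)  # exon15 == mut coords
  list(pair = pair,
       ground_truth_differential = as.integer(gt),
       occluded_wt = as.integer(gt),
       spec = spec)
}

#' Simulate a dose-response experiment
#'
#' Draws residual-expression responses from a 4PL curve plus Gaussian
#' noise on a dose grid, in the table dialect the assay module reads.
#' The default grid spans the working concentrations 10-100 nM.
#'
#' @param ic50,top,bottom,hill True curve parameters (IC50 in nM).
#' @param doses Dose grid (nM).
#' @param replicates Replicates per dose.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param design,allele Labels for the output table.
#' @param path Optional TSV output path.
#' @return data.frame with columns `design`, `allele`, `dose_nM`,
#'   `replicate`, `fold_change`.
#' @export
generate_dose_response <- function(ic50, top = 1, bottom = 0, hill = 1,
                                   doses = c(10, 20, 40, 80, 100),
                                   replicates = 3L, noise_sd = 0.05,
                                   seed = 1L, design = "ASO", allele = "mut",
                                   path = NULL) {
  stopifnot(ic50 > 0, noise_sd >= 0, replicates >= 1L)
  set.seed(seed)
  d <- rep(doses, each = replicates)
  y <- fourpl(d, top, bottom, log10(ic50), hill) +
    stats::rnorm(length(d), 0, noise_sd)
  out <- data.frame(design = design, allele = allele, dose_nM = d,
                    replicate = rep(seq_len(replicates), times = length(doses)),
                    fold_change = y, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Load the packaged 28-design reference table
#'
#' The fixture transcribes the published design table: name, published
#' category, notation, and the printed length / DNA-gap / GC% / Tm /
#' off-target / per-allele binding-affinity columns. Every notation is
#' parsed and re-measured, and per-row consistency flags record where the
#' printed metadata disagrees with the printed sequence (two rows carry
#' such conflicts; they are flagged, not corrected).
#'
#' @param path Fixture TSV (defaults to the copy shipped with the
#'   package).
#' @return data.frame with the printed columns plus `parsed_length`,
#'   `gc_computed`, `gap_computed` (longest PS-DNA run),
#'   `inferred_category`, `dna_runs` (comma-separated), and logical
#'   `length_consistent`, `gap_consistent`, `gc_consistent`. Attribute
#'   `designs` holds the parsed `oligo_design` list, named by design.
#' @export
load_table1 <- function(path = system.file("extdata", "table1_asos.tsv",
                                           package = "asodesign")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  designs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    mm <- if (is.na(df$mismatch_position[i])) integer(0) else df$mismatch_position[i]
    designs[[i]] <- tryCatch(
      parse_oligo_notation(df$notation[i], name = df$name[i],
                           mismatch_positions = mm),
      error = function(e) stop("fixture integrity: record '", df$name[i],
                               "' failed to parse: ", conditionMessage(e),
                               call. = FALSE))
  }
  names(designs) <- df$name
  df$parsed_length <- vapply(designs, function(d) nrow(d$residues), integer(1))
  df$gc_computed <- vapply(designs, gc_content, numeric(1))
  runs <- lapply(designs, function(d) dna_run_profile(d)$runs)
  df$gap_computed <- vapply(runs, function(r) if (length(r)) max(r) else 0L, integer(1))
  df$dna_runs <- vapply(runs, paste, character(1), collapse = ",")
  df$inferred_category <- vapply(designs, function(d)
    infer_category(d$residues), character(1))
  df$length_consistent <- df$parsed_length == df$length_printed
  df$gap_consistent <- df$gap_computed == df$gap_printed
  df$gc_consistent <- abs(df$gc_computed - df$gc_printed) < 0.06
  if (nrow(df) != 28L) {
    stop("fixture integrity: expected 28 records, found ", nrow(df), call. = FALSE)
  }
  counts <- table(df$paper_category)
  if (!identical(as.integer(counts[c("gapmer", "mixmer", "mismatch_mixmer")]),
                 c(15L, 7L, 6L))) {
    stop("fixture integrity: category counts are not 15/7/6", call. = FALSE)
  }
  attr(df, "designs") <- designs
  df
}

#' Load the packaged table of reported IC50 values
#'
#' Per-design mutant and wild-type IC50 values (nM) from the published
#' dose-response experiments, used as inputs to the selectivity
#' arithmetic.
#'
#' @param path Fixture TSV (defaults to the packaged copy).
#' @return data.frame with columns `design`, `ic50_mut_nM`, `ic50_wt_nM`.
#' @export
load_reported_ic50 <- function(path = system.file("extdata", "reported_ic50.tsv",
                                                  package = "asodesign")) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
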
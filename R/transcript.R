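#' Construct an exon
#'
#' Exons are the building blocks of the transcript model. The sequence is
#' normalized to the RNA alphabet (T becomes U) and must be non-empty.
#'
#' @param id Character label, e.g. `"exon15"`.
#' @param sequence Nucleotide string (A/C/G/U or T).
#' @return An object of class `exon` with fields `id` and `sequence`.
#' @examples
#' exon("exon16", "GGGACU")
#' @export
exon <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) == 0L) stop("exon sequence must be non-empty", call. = FALSE)
  structure(list(id = id, sequence = sequence), class = "exon")
}

#' Build the wild-type / exon-skipped transcript pair
#'
#' Concatenates the exons into the wild-type transcript and, omitting the
#' exon at `skip_index`, into the mutant (exon-skipped) transcript. The
#' novel junction created by the skip, the coordinate map between alleles
#' and the in-frame status of the deletion are recorded. Only internal
#' exons may be skipped: removing a terminal exon creates no novel
#' junction.
#'
#' All coordinates are 0-based, half-open; junctions are inter-residue
#' offsets (the boundary between positions j-1 and j).
#'
#' @param exons List of [exon()] objects, 5' to 3'.
#' @param skip_index 1-based index of the exon to skip (must be internal).
#' @return An object of class `transcript_pair` with fields
#'   `wt_sequence`, `mut_sequence`, `wt_junction`, `mut_junction`,
#'   `skipped_length`, `in_frame`, `skipped_exon_id`, and per-allele exon
#'   coordinate tables `exons_wt`, `exons_mut` (columns id/start/end,
#'   0-based half-open).
#' @examples
#' p <- build_junction_pair(list(exon("A", "AAA"), exon("B", "CCC"),
#'                               exon("C", "GGG")), skip_index = 2)
#' p$mut_sequence  # "AAAGGG"
#' @export
build_junction_pair <- function(exons, skip_index) {
  if (length(exons) < 3L) {
    stop("need at least 3 exons so the skipped exon is internal", call. = FALSE)
  }
  stopifnot(all(vapply(exons, inherits, logical(1), "exon")))
  if (skip_index <= 1L || skip_index >= length(exons)) {
    stop("skip_index must name an internal exon (terminal skips create no junction)",
         call. = FALSE)
  }
  seqs <- vapply(exons, `[[`, character(1), "sequence")
  ids <- vapply(exons, `[[`, character(1), "id")
  lens <- nchar(seqs)

  wt_sequence <- paste(seqs, collapse = "")
  mut_sequence <- paste(seqs[-skip_index], collapse = "")
  starts_wt <- cumsum(c(0L, lens))[seq_along(lens)]
  wt_junction <- starts_wt[skip_index]
  mut_junction <- wt_junction  # identical prefix up to the skipped exon
  skipped_length <- lens[skip_index]

  mut_lens <- lens[-skip_index]
  starts_mut <- cumsum(c(0L, mut_lens))[seq_along(mut_lens)]

  structure(list(
    wt_sequence = wt_sequence,
    mut_sequence = mut_sequence,
    wt_junction = wt_junction,
    mut_junction = mut_junction,
    skipped_length = skipped_length,
    in_frame = (skipped_length %% 3L == 0L),
    skipped_exon_id = ids[skip_index],
    exons_wt = data.frame(id = ids, start = starts_wt,
                          end = starts_wt + lens, stringsAsFactors = FALSE),
    exons_mut = data.frame(id = ids[-skip_index], start = starts_mut,
                           end = starts_mut + mut_lens, stringsAsFactors = FALSE)
  ), class = "transcript_pair")
}

#' Map mutant-transcript positions to wild-type positions
#'
#' Identity left of the novel junction; shifted by the skipped-exon length
#' at and right of it. Total and strictly increasing over valid mutant
#' positions.
#'
#' @param pair A [build_junction_pair()] result.
#' @param pos Integer vector of 0-based mutant positions.
#' @return Integer vector of 0-based wild-type positions.
#' @export
map_mut_to_wt <- function(pair, pos) {
  stopifnot(inherits(pair, "transcript_pair"))
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= nchar(pair$mut_sequence))) {
    stop("position outside the mutant transcript", call. = FALSE)
  }
  ifelse(pos < pair$mut_junction, pos, pos + pair$skipped_length)
}

#' @export
print.transcript_pair <- function(x, ...) {
  cat(sprintf("transcript_pair: wt %d nt / mut %d nt; skipped '%s' (%d nt, %s)\n",
              nchar(x$wt_sequence), nchar(x$mut_sequence), x$skipped_exon_id,
              x$skipped_length, if (x$in_frame) "in-frame" else "out-of-frame"))
  cat(sprintf("  junction offsets: wt %d, mut %d\n", x$wt_junction, x$mut_junction))
  invisible(x)
}

#' Extract junction-centered analysis windows
#'
#' For each requested length L, cuts a window from each allele with its
#' junction at offset floor(L/2): the wild-type window is centered on the
#' boundary upstream of the skipped exon, the mutant window on the novel
#' junction. Windows that would run past a transcript end are truncated to
#' the available sequence and flagged.
#'
#' @param pair A [build_junction_pair()] result.
#' @param lengths Integer vector of window lengths (each >= 2). Defaults
#'   to the six analysis lengths 200, 500, 1000, 1500, 2000 and 2500 nt.
#' @return A list of windows, each of class `transcript_window` with
#'   fields `allele` ("wt"/"mut"), `length_requested`, `sequence`,
#'   `offset` (0-based offset into the parent transcript),
#'   `junction_offset` (junction position within the window) and
#'   `truncated`.
#' @export
extract_centered_windows <- function(pair,
                                     lengths = c(200L, 500L, 1000L, 1500L,
                                                 2000L, 2500L)) {
  stopifnot(inherits(pair, "transcript_pair"))
  lengths <- as.integer(lengths)
  if (any(lengths < 2L)) stop("window lengths must be >= 2", call. = FALSE)

  one <- function(allele, L) {
    seqs <- if (allele == "wt") pair$wt_sequence else pair$mut_sequence
    j <- if (allele == "wt") pair$wt_junction else pair$mut_junction
    n <- nchar(seqs)
    start <- j - L %/% 2L
    end <- start + L
    truncated <- start < 0L || end > n
    start_c <- max(0L, start)
    end_c <- min(n, end)
    structure(list(
      allele = allele,
      length_requested = L,
      sequence = substr(seqs, start_c + 1L, end_c),
      offset = start_c,
      junction_offset = j - start_c,
      truncated = truncated
    ), class = "transcript_window")
  }

  out <- list()
  for (L in lengths) {
    out[[length(out) + 1L]] <- one("wt", L)
    out[[length(out) + 1L]] <- one("mut", L)
  }
  out
}

#' Read transcripts from a FASTA file
#'
#' @param path FASTA file.
#' @param alphabet Normalize to `"RNA"` (default, T -> U) or keep `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_transcripts_fasta <- function(path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  if (alphabet == "RNA") out <- vapply(out, normalize_rna, character(1))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param alphabet `"RNA"` (default) or `"DNA"` (U -> T on output).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  if (alphabet == "DNA") seqs <- chartr("Uu", "Tt", seqs)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read an exon table
#'
#' TSV with columns `id` and `sequence`; rows in 5' to 3' order.
#'
#' @param path TSV file.
#' @return List of [exon()] objects.
#' @export
read_exon_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(df))) {
    stop("exon table needs columns 'id' and 'sequence'", call. = FALSE)
  }
  Map(exon, df$id, df$sequence)
}
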
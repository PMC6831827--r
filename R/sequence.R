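#' Create a sequence record
#'
#' A sequence record couples a one-letter amino-acid string with the residue
#' number of its first position, so that all downstream region arithmetic can
#' use the numbering of the full-length protein (JIP3 numbering throughout
#' this package).
#'
#' @param id Character identifier.
#' @param residues One-letter amino-acid string (20 standard codes only).
#' @param first_residue_number Residue number of the first position (>= 1).
#' @return An object of class `seq_record`.
#' @export
#' @examples
#' seq_record("demo", "LEALEGK", first_residue_number = 10)
seq_record <- function(id, residues, first_residue_number = 1L) {
  stopifnot(is.character(id), length(id) == 1,
            is.character(residues), length(residues) == 1, nchar(residues) > 0)
  first_residue_number <- as.integer(first_residue_number)
  if (is.na(first_residue_number) || first_residue_number < 1) {
    abort("first_residue_number must be an integer >= 1")
  }
  check_residues(residues, id)
  structure(
    list(id = id, residues = residues,
         first_residue_number = first_residue_number),
    class = "seq_record"
  )
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  residues %d-%d (%d aa)\n", x$id,
              x$first_residue_number,
              x$first_residue_number + nchar(x$residues) - 1L,
              nchar(x$residues)))
  cat(x$residues, "\n")
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

#' @export
as.character.seq_record <- function(x, ...) x$residues

seq_residues <- function(x) {
  if (inherits(x, "seq_record")) strsplit(x$residues, "")[[1]]
  else strsplit(x, "")[[1]]
}

#' Residue numbers covered by a record
#' @param seq A [seq_record()].
#' @return Integer vector of residue numbers.
#' @export
residue_numbers <- function(seq) {
  seq$first_residue_number + seq_len(length(seq)) - 1L
}

#' Extract a residue range from a record
#'
#' Residue numbers are inclusive and interpreted in the record's own
#' numbering (e.g. `extract_region(jip3, 74, 177)` returns the 104-residue
#' LZI coiled-coil segment).
#'
#' @param seq A [seq_record()].
#' @param start,end Inclusive residue numbers; `start <= end` and the range
#'   must lie within the record.
#' @return A `seq_record` whose `first_residue_number` is `start`.
#' @export
extract_region <- function(seq, start, end) {
  stopifnot(inherits(seq, "seq_record"))
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) abort(sprintf("inverted region bounds [%d-%d]", start, end))
  rn <- residue_numbers(seq)
  if (start < rn[1] || end > rn[length(rn)]) {
    abort(sprintf("region [%d-%d] outside record %s (%d-%d)",
                  start, end, seq$id, rn[1], rn[length(rn)]))
  }
  i <- start - seq$first_residue_number + 1L
  j <- end - seq$first_residue_number + 1L
  seq_record(sprintf("%s[%d-%d]", seq$id, start, end),
             substr(seq$residues, i, j), start)
}

#' Ungapped percent identity between two equal-length records
#'
#' Position-by-position identity with no gaps, as used for the fixed,
#' length-matched RH1 and LZI ranges of the JIP3/JIP4 homologs.
#'
#' @param a,b [seq_record()]s (or plain strings) of equal length.
#' @return Percent identity, rounded to one decimal.
#' @export
percent_identity <- function(a, b) {
  ra <- seq_residues(a); rb <- seq_residues(b)
  if (length(ra) != length(rb)) {
    abort(sprintf("ungapped identity needs equal lengths (%d vs %d)",
                  length(ra), length(rb)))
  }
  round(100 * mean(ra == rb), 1)
}

#' Number of complete heptad repeats in a region
#'
#' @param region_length Non-negative region length in residues.
#' @return `floor(region_length / 7)`.
#' @export
#' @examples
#' count_complete_heptads(104) # the 14 heptads of the LZI
count_complete_heptads <- function(region_length) {
  region_length <- as.numeric(region_length)
  if (any(is.na(region_length)) || any(region_length < 0)) {
    abort("region_length must be >= 0")
  }
  as.integer(floor(region_length / 7))
}

#' Assign a cyclic heptad register string
#'
#' @param region A [seq_record()] (or a plain string); only its length is
#'   used.
#' @param phase_of_first Register letter (`"a"`-`"g"`) of the first residue.
#' @return A string of register letters of the region length.
#' @export
#' @examples
#' assign_heptad_register(seq_record("x", "LEALEGKLE"), "f")
assign_heptad_register <- function(region, phase_of_first = "a") {
  n <- if (inherits(region, "seq_record")) length(region) else nchar(region)
  k <- match(phase_of_first, letters[1:7])
  if (is.na(k)) abort("phase_of_first must be one of a-g")
  paste(letters[1:7][((k - 1 + seq_len(n) - 1) %% 7) + 1], collapse = "")
}

#' Find the heptad phase that maximizes hydrophobic core occupancy
#'
#' Scans the seven possible phases and returns the one placing the largest
#' fraction of hydrophobic residues (Ile/Leu/Val/Met/Phe by default) at the
#' core `a`/`d` positions.
#'
#' @param region A [seq_record()].
#' @param core_residues Residues counted as hydrophobic core.
#' @return A list with `phase`, `fraction` (a/d hydrophobic occupancy) and
#'   the full `register` string.
#' @export
best_heptad_phase <- function(region,
                              core_residues = c("I", "L", "V", "M", "F")) {
  res <- seq_residues(region)
  occ <- vapply(letters[1:7], function(ph) {
    reg <- seq_residues(assign_heptad_register(region, ph))
    mean(res[reg %in% c("a", "d")] %in% core_residues)
  }, numeric(1))
  ph <- names(which.max(occ))
  list(phase = ph, fraction = unname(max(occ)),
       register = assign_heptad_register(region, ph))
}

#' Helical residue count implied by a helix-content percentage
#'
#' Converts a circular-dichroism helix fraction into a residue count, e.g.
#' 81.1% of 166 residues -> 135 helical residues.
#'
#' @param helix_fraction Percentage in `[0, 100]`.
#' @param n_residues Number of residues the fraction applies to.
#' @return Nearest integer of `helix_fraction/100 * n_residues`.
#' @export
helix_residue_count <- function(helix_fraction, n_residues) {
  if (any(helix_fraction < 0) || any(helix_fraction > 100)) {
    abort("helix_fraction must be within [0, 100]")
  }
  as.integer(round(helix_fraction / 100 * n_residues))
}

#' Average-mass molecular weight of a construct, in kDa
#'
#' Sums average residue masses plus one water. By default the Gly-Ser-His
#' remnant of the thrombin-cleaved expression tag is prepended, matching the
#' constructs used for the biophysical characterization.
#'
#' @param seq A [seq_record()] (or plain string).
#' @param nterm_extra Residues prepended to the construct (default `"GSH"`;
#'   use `""` for none).
#' @return Mass in kDa (full precision; round to 0.1 for table-style
#'   reporting).
#' @export
#' @examples
#' sequence_mass_kda(seq_record("gly", "G"), nterm_extra = "")
sequence_mass_kda <- function(seq, nterm_extra = "GSH") {
  res <- seq_residues(seq)
  extra <- if (nzchar(nterm_extra)) seq_residues(check_residues(nterm_extra, "nterm_extra")) else character()
  (sum(AA_MASS[c(extra, res)]) + WATER_MASS) / 1000
}

#' Canonical region annotations for the JIP3 N-terminal tandem
#'
#' Returns the residue ranges used throughout the package, in JIP3
#' numbering: the RH1 four-helix-bundle domain and its helices, the
#' inter-domain hinge, the LZI coiled coil and the termini. The modelling
#' ranges (alpha1 26-43, alpha2 50-73, hinge 74-77 helical, coil 78-180,
#' C-terminal helical continuation 181-187) complement the domain-level
#' annotations RH1 22-73 / LZI 74-177.
#'
#' @return A tibble with columns `name`, `start`, `end`, `role`.
#' @export
jip_regions <- function() {
  tibble(
    name = c("nterm_tag", "nterm", "rh1", "alpha1", "loop", "alpha2",
             "hinge", "lzi", "coil", "cterm"),
    start = c(19L, 22L, 22L, 26L, 44L, 50L, 74L, 74L, 78L, 181L),
    end = c(21L, 25L, 73L, 43L, 49L, 73L, 77L, 177L, 180L, 187L),
    role = c("tag remnant (GSH)", "coil", "domain", "helix", "coil",
             "helix", "helix", "domain", "coiled coil", "helix")
  )
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param first_residue_numbers Optional named (by record) or unnamed integer
#'   vector of first residue numbers; a `first_residue=<n>` token in a FASTA
#'   header is honoured otherwise.
#' @return Named list of [seq_record()]s.
#' @export
read_fasta <- function(path, first_residue_numbers = NULL) {
  fas <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                            whole.header = TRUE)
  out <- lapply(seq_along(fas), function(i) {
    header <- attr(fas[[i]], "Annot")
    if (is.null(header)) header <- names(fas)[i]
    id <- sub("^>?\\s*", "", strsplit(header, "\\s+")[[1]][1])
    first <- 1L
    m <- regmatches(header, regexpr("first_residue=\\d+", header))
    if (length(m) == 1) first <- as.integer(sub("first_residue=", "", m))
    if (!is.null(first_residue_numbers)) {
      first <- if (!is.null(names(first_residue_numbers))) {
        as.integer(first_residue_numbers[[id]])
      } else {
        as.integer(first_residue_numbers[i])
      }
    }
    seq_record(id, toupper(as.character(fas[[i]])), first)
  })
  names(out) <- vapply(out, function(r) r$id, "")
  out
}

#' Write sequence records to a FASTA file
#'
#' @param seqs A list of [seq_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "seq_record")) seqs <- list(seqs)
  headers <- vapply(seqs, function(r) {
    sprintf("%s first_residue=%d", r$id, r$first_residue_number)
  }, "")
  seqinr::write.fasta(lapply(seqs, function(r) r$residues),
                      names = headers, file.out = path, as.string = TRUE)
  invisible(path)
}

#' Packaged sequence fixtures
#'
#' Loads the synthetic stand-in records for the N-terminal regions of human
#' JIP3 (residues 1-187), human JIP4 (1-182) and the mouse JIP3 construct
#' region (22-187, one Lys->Arg difference from human), plus a poly-heptad
#' demo sequence. The records are constructed to honour the published
#' residue-level description of the region (see the fixture manifest); they
#' are not transcriptions of the database entries. File integrity is checked
#' against the packaged md5 manifest.
#'
#' @return Named list of [seq_record()]s: `jip3`, `jip4`, `jip3_mouse`,
#'   `heptad_demo`.
#' @export
fixture_sequences <- function() {
  fa <- system.file("extdata", "jip_nterm_synthetic.fasta",
                    package = "jiptandem", mustWork = TRUE)
  man <- system.file("extdata", "fixture_manifest.tsv",
                     package = "jiptandem", mustWork = TRUE)
  tab <- read.table(man, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  want <- tab$md5[tab$file == basename(fa)]
  got <- unname(tools::md5sum(fa))
  if (length(want) != 1 || !identical(want, got)) {
    abort("fixture checksum mismatch: packaged FASTA does not match manifest")
  }
  recs <- read_fasta(fa)
  list(jip3 = recs[["JIP3_HUMAN_NTERM"]],
       jip4 = recs[["JIP4_HUMAN_NTERM"]],
       jip3_mouse = recs[["JIP3_MOUSE_CONSTRUCT"]],
       heptad_demo = recs[["HEPTAD_DEMO"]])
}

#' The modelled construct record: GSH tag remnant plus a residue range
#'
#' Prepends the Gly-Ser-His tag remnant (numbered `start - 3` to
#' `start - 1`, i.e. 19-21 for the standard 22-187 construct) to a region of
#' a record.
#'
#' @param seq A [seq_record()] covering the range.
#' @param start,end Residue range of the construct (default 22-187).
#' @return A `seq_record` beginning with `GSH`.
#' @export
construct_record <- function(seq, start = 22L, end = 187L) {
  reg <- extract_region(seq, start, end)
  seq_record(sprintf("GSH+%s", reg$id),
             paste0("GSH", reg$residues), reg$first_residue_number - 3L)
}
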
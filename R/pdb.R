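#' Write a model as fixed-column PDB ATOM records
#'
#' One CA atom per residue, chains as stored, occupancy 1.00, B-factor
#' 0.00.
#'
#' @param m A `protein_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(m, path) {
  stopifnot(inherits(m, "protein_model"))
  lines <- character(0)
  serial <- 0L
  for (ch in unique(m$chain)) {
    sub <- m[m$chain == ch, ]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, AA_THREE[[sub$res[i]]], ch, sub$resno[i],
        sub$x[i], sub$y[i], sub$z[i], 1.00, 0.00))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial, AA_THREE[[sub$res[nrow(sub)]]], ch,
                              sub$resno[nrow(sub)]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PDB file into a model
#'
#' Parses ATOM records (via bio3d) and keeps one center per residue: the CA
#' atom where present, otherwise the first atom of the residue. Round trips
#' with [write_pdb()] preserve chain ids, residue numbers and coordinates to
#' 0.001 Angstrom.
#'
#' @param path PDB file path.
#' @return A `protein_model`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) {
                    abort(sprintf("failed to parse PDB %s: %s", path,
                                  conditionMessage(e)))
                  })
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) abort(sprintf("no ATOM records in %s", path))
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) ca <- at[!duplicated(paste(at$chain, at$resno)), ]
  res1 <- AA_ONE[ca$resid]
  if (anyNA(res1)) {
    abort(sprintf("non-standard residue name(s) in %s: %s", path,
                  paste(unique(ca$resid[is.na(res1)]), collapse = ", ")))
  }
  new_protein_model(tibble(chain = ca$chain, resno = ca$resno,
                           res = unname(res1), x = ca$x, y = ca$y, z = ca$z),
                    provenance = sprintf("read from %s", basename(path)))
}
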
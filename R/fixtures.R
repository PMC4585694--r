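#' Packaged mature human calmodulin sequence
#'
#' The 148-residue mature human calmodulin (CaM) sequence shipped with
#' the package as a worked reference: CaM carries nine Met residues
#' (positions 36, 51, 71, 72, 76, 109, 124, 144, 145) and nine Leu
#' residues (4, 18, 32, 39, 48, 69, 105, 112, 116) under mature-protein
#' numbering.
#'
#' @return one-letter sequence string of length 148.
#' @export
cam_sequence <- function() {
  lines <- readLines(cam_fasta_path())
  paste(lines[!startsWith(lines, ">")], collapse = "")
}

#' Path to the packaged calmodulin FASTA file
#' @return file path.
#' @export
cam_fasta_path <- function() {
  system.file("extdata", "calmodulin_human.fasta", package = "frustrace",
              mustWork = TRUE)
}
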
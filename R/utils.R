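# Shared low-level helpers: classed errors, base/codon utilities.

stop_structmapr <- function(msg, class) {
  stop(structure(
    class = c(class, "structmapr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error <- function(msg) stop_structmapr(msg, "structmapr_format_error")
model_error  <- function(msg) stop_structmapr(msg, "structmapr_model_error")
range_error  <- function(msg) stop_structmapr(msg, "structmapr_range_error")
lookup_error <- function(msg) stop_structmapr(msg, "structmapr_lookup_error")
usage_error  <- function(msg) stop_structmapr(msg, "structmapr_usage_error")
param_error  <- function(msg) stop_structmapr(msg, "structmapr_param_error")

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  SEC = "U", PYL = "O", UNK = "X"
)
AA_1TO3 <- stats::setNames(names(AA_3TO1), unname(AA_3TO1))

#' Translate one codon with the standard genetic code
#'
#' Codons containing ambiguity characters (e.g. N) translate to `"X"`; stop
#' codons translate to `"*"`.
#'
#' @param codon character vector of 3-letter DNA strings.
#' @return character vector of 1-letter amino-acid codes.
#' @keywords internal
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Complement of DNA base characters (vectorised, N-safe)
#' @keywords internal
complement_base <- function(base) {
  out <- DNA_COMPLEMENT[base]
  if (anyNA(out)) format_error(sprintf(
    "cannot complement non-DNA character(s): %s",
    paste(unique(base[is.na(out)]), collapse = ", ")))
  unname(out)
}

#' Residue three-letter to one-letter conversion (tolerant of 1-letter input)
#' @keywords internal
res_name_to_one <- function(res_name) {
  res_name <- toupper(res_name)
  one <- ifelse(nchar(res_name) == 1L & res_name %in% AA_ALPHABET,
                res_name, unname(AA_3TO1[res_name]))
  one[is.na(one)] <- "X"
  one
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a
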
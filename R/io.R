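# Dataset tables and SMILES files.

#' Read a sensitivity dataset
#'
#' Reads the standard training table: a UTF-8 CSV with header columns `id`,
#' `smiles` and one or more `sens_<metal>` columns holding potentiometric
#' sensitivities in mV/decade. Empty sensitivity cells become `NA` (a metal
#' not measured for that ionophore), never zero.
#'
#' @param path CSV file path.
#' @return data frame with character `id`, `smiles` and numeric `sens_*`
#'   columns; zero rows for a header-only file.
#' @export
read_sensitivity_data <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "smiles")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read_sensitivity_data: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  sens <- grep("^sens_", names(df), value = TRUE)
  if (length(sens) == 0L) {
    stop("read_sensitivity_data: no sens_<metal> column found")
  }
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    stop("read_sensitivity_data: duplicate ids: ", paste(dup, collapse = ", "))
  }
  for (s in sens) {
    v <- trimws(df[[s]])
    v[v == ""] <- NA_character_
    df[[s]] <- as.numeric(v)
    bad <- !is.na(df[[s]]) & !is.finite(df[[s]])
    if (any(bad)) stop("read_sensitivity_data: non-finite sensitivity in ", s)
  }
  df[, c(need, sens), drop = FALSE]
}

#' Write a sensitivity dataset
#'
#' Inverse of [read_sensitivity_data()]: `NA` sensitivities are written as
#' empty cells so the round trip is exact.
#'
#' @param data data frame with `id`, `smiles` and `sens_*` columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a .smi file
#'
#' One molecule per line: a SMILES string, whitespace, then an id. Lines that
#' are blank or start with `#` are skipped. Missing ids default to the line
#' number.
#'
#' @param path .smi file path.
#' @return data frame with columns `id` and `smiles`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(data.frame(id = character(0), smiles = character(0)))
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, "", 1L)
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) >= 2L) parts[[k]][2L] else as.character(k)
  }, "")
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' The four diphenylphosphoryl acetamide candidate ionophores
#'
#' SMILES for the four bis(diphenylphosphoryl) ketone ionophores whose
#' sensitivities the trained models are meant to predict, encoded from their
#' IUPAC names. Substances 1-3 are N,N'-dioctyl diamines whose two nitrogen
#' atoms are joined by an alkane-diyl linker and each carry a
#' 1-(diphenylphosphoryl)propan-2-one arm; substance 4 replaces the diamine
#' by a piperazine with two 2-(diphenylphosphoryl)acetyl groups.
#'
#' The published names give substances 1 and 2 the same butane-1,4-diyl
#' linker, which contradicts the discussed linker-length series 1 < 2 < 3;
#' the shipped encoding of substance 2 is therefore a reconstruction with a
#' pentane-1,5-diyl linker. Use `substance2_linker` to encode a different
#' assumption.
#'
#' @param substance2_linker number of CH2 units in the substance 2 linker
#'   (default 5, the reconstructed value; 4 reproduces the printed name).
#' @return data frame with columns `id`, `smiles`, `reconstructed`.
#' @export
table1_ionophores <- function(substance2_linker = 5L) {
  arm <- "CC(=O)CP(=O)(c1ccccc1)c1ccccc1"   # -CH2-C(=O)-CH2-P(=O)Ph2
  linker <- function(k) paste(rep("C", k), collapse = "")
  di <- function(k) sprintf("CCCCCCCCN(%sN(CCCCCCCC)%s)%s",
                            linker(k), arm, arm)
  data.frame(
    id = c("substance1", "substance2", "substance3", "substance4"),
    smiles = c(
      di(4L),
      di(as.integer(substance2_linker)),
      di(6L),
      "O=C(CP(=O)(c1ccccc1)c1ccccc1)N1CCN(C(=O)CP(=O)(c2ccccc2)c2ccccc2)CC1"),
    reconstructed = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}
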
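#' Read protein-to-GO annotations
#'
#' `read_gaf()` reads GAF 2.x (protein id from column 2, GO id from column 5,
#' evidence code from column 7; comment lines starting with `!` skipped).
#' `read_annotation_tsv()` reads a plain 2-column `protein<TAB>GO` table.
#'
#' @param path File path.
#' @param experimental_only If `TRUE`, keep only experimentally supported
#'   evidence codes (EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC); by default
#'   electronically inferred (IEA) annotations are kept as well.
#' @return A tibble with columns `protein`, `go` (and `evidence` for GAF).
#' @export
read_gaf <- function(path, experimental_only = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) return(tibble(protein = character(), go = character(),
                                    evidence = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 7L)) {
    abort("GAF rows must have at least 7 tab-separated columns")
  }
  out <- tibble(
    protein = map_chr(parts, 2),
    go = map_chr(parts, 5),
    evidence = map_chr(parts, 7)
  )
  if (experimental_only) {
    out <- dplyr::filter(out, .data$evidence %in%
                           c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC"))
  }
  out
}

#' @rdname read_gaf
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein", "go"),
                          colClasses = "character", quote = "")
  as_tibble(df)
}

#' Read protein-to-domain assignments
#'
#' `read_interproscan_tsv()` reads InterProScan tabular output (protein
#' accession in column 1, InterPro entry in column 12; rows without an
#' InterPro id, shown as `-`, are dropped). `read_domain_tsv()` reads a plain
#' 2-column `protein<TAB>domain` table.
#'
#' @param path File path.
#' @return A tibble with columns `protein`, `domain`.
#' @export
read_interproscan_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && any(lengths(parts) < 12L)) {
    abort("InterProScan TSV rows must have at least 12 columns")
  }
  out <- tibble(
    protein = map_chr(parts, 1),
    domain = map_chr(parts, 12)
  )
  dplyr::distinct(dplyr::filter(out, .data$domain != "-" & nzchar(.data$domain)))
}

#' @rdname read_interproscan_tsv
#' @export
read_domain_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein", "domain"),
                          colClasses = "character", quote = "")
  as_tibble(df)
}

#' Read a domain-to-GO mapping in InterPro2GO flat format
#'
#' Lines look like
#' `InterPro:IPR000001 Kringle > GO:protein binding ; GO:0005515`;
#' comment lines start with `!`.
#'
#' @param path File path.
#' @return A tibble with columns `domain`, `go`.
#' @export
read_interpro2go <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  m <- regmatches(lines,
                  regexec("^InterPro:(\\S+).*;\\s*(GO:\\d+)\\s*$", lines))
  ok <- lengths(m) == 3L
  if (any(!ok)) {
    abort(paste0("unparseable InterPro2GO line: '", lines[!ok][1], "'"))
  }
  tibble(domain = map_chr(m, 2), go = map_chr(m, 3))
}

#' Read DIAMOND/BLAST tabular output
#'
#' Reads the 12-column `outfmt 6` dialect: query id (column 1), subject id
#' (column 2) and bit-score (column 12) are used.
#'
#' @param path File path.
#' @return A tibble with columns `query`, `subject`, `bits`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(query = character(), subject = character(), bits = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12L)) {
    abort("BLAST tabular rows must have 12 tab-separated columns")
  }
  out <- tibble(
    query = map_chr(parts, 1),
    subject = map_chr(parts, 2),
    bits = as.numeric(map_chr(parts, 12))
  )
  if (any(is.na(out$bits)) || any(out$bits < 0)) {
    abort("bit-scores must be non-negative numbers")
  }
  out
}

#' Read a STRING-style PPI edge list
#'
#' Whitespace-separated `protein1 protein2 combined_score` rows (an optional
#' header naming those columns is skipped). Scores above 1 are interpreted as
#' being on STRING's 0-1000 scale and divided by 1000.
#'
#' @param path File path.
#' @return A tibble with columns `protein1`, `protein2`, `weight` in
#'   `[0, 1]`.
#' @export
read_string_links <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("protein1", lines[[1]])) lines <- lines[-1]
  if (!length(lines)) {
    return(tibble(protein1 = character(), protein2 = character(),
                  weight = numeric()))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) < 3L)) abort("STRING rows need 3 whitespace-separated fields")
  w <- as.numeric(map_chr(parts, 3))
  if (any(is.na(w)) || any(w < 0)) abort("combined scores must be non-negative")
  if (any(w > 1)) w <- w / 1000
  tibble(protein1 = map_chr(parts, 1), protein2 = map_chr(parts, 2),
         weight = w)
}

#' Write and read CAFA-style prediction files
#'
#' Three tab-separated columns: target protein id, GO id, and the score
#' formatted with two decimals. `header` lines, when given, are written
#' verbatim before the records and an `END` line is appended.
#'
#' @param scores A tibble with columns `protein`, `go`, `score`.
#' @param path Output path.
#' @param header Optional character vector of header lines.
#' @return `path`, invisibly (`write_predictions`); a tibble with columns
#'   `protein`, `go`, `score` (`read_predictions`).
#' @export
write_predictions <- function(scores, path, header = NULL) {
  stopifnot(all(c("protein", "go", "score") %in% names(scores)))
  lines <- sprintf("%s\t%s\t%.2f", scores$protein, scores$go, scores$score)
  if (!is.null(header)) lines <- c(header, lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("\t", lines, fixed = TRUE)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  tibble(
    protein = map_chr(parts, 1),
    go = map_chr(parts, 2),
    score = as.numeric(map_chr(parts, 3))
  )
}

#' Write a co-occurrence table as a 3-column TSV
#'
#' Writes `domain`, `go`, `p_cond` for inspection or downstream use.
#'
#' @param table A [cooccurrence table][conditional_probabilities].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cooccurrence_tsv <- function(table, path) {
  utils::write.table(
    data.frame(domain = table$domain, go = table$go,
               p_cond = sprintf("%.10g", table$p_cond)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
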
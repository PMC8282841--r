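#' Construct a dominant-marker band matrix
#'
#' The central data container of the package: a table of 0/1 band-presence
#' scores for a set of individuals (rows) at a set of dominant-marker loci
#' (columns), together with the primer that amplified each locus and the
#' population each individual was sampled from. Missing scores are `NA`.
#'
#' @param data integer/numeric matrix of 0, 1 and `NA`; rows are
#'   individuals, columns are loci. Dimnames, if present, are used as
#'   default ids.
#' @param individual_ids character vector of unique individual labels.
#' @param locus_ids character vector of unique locus labels.
#' @param primer_of character vector (length = loci) giving the amplifying
#'   primer of each locus, or `NULL` to parse it from locus ids of the
#'   form `"PRIMER:index"`.
#' @param population_of character/factor vector (length = individuals)
#'   giving the population label of each individual. A single population
#'   is assumed when omitted.
#'
#' @return An object of class `band_matrix`: a list with elements `data`
#'   (integer matrix with dimnames), `primer_of` (named character) and
#'   `population_of` (named factor).
#' @examples
#' m <- band_matrix(matrix(c(1, 0, 0, 1), 2, 2),
#'                  individual_ids = c("i1", "i2"),
#'                  locus_ids = c("P1:1", "P1:2"),
#'                  population_of = c("A", "B"))
#' summary(m)
#' @export
band_matrix <- function(data, individual_ids = rownames(data),
                        locus_ids = colnames(data), primer_of = NULL,
                        population_of = NULL) {
  data <- as.matrix(data)
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(data)))
  if (is.null(locus_ids))
    locus_ids <- paste0("L:", seq_len(ncol(data)))
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)

  if (nrow(data) < 2L)
    stop("a band matrix needs at least 2 individuals", call. = FALSE)
  if (ncol(data) < 1L)
    stop("a band matrix needs at least 1 locus", call. = FALSE)
  if (length(individual_ids) != nrow(data) || anyDuplicated(individual_ids))
    stop("individual_ids must be unique and match the number of rows",
         call. = FALSE)
  if (length(locus_ids) != ncol(data) || anyDuplicated(locus_ids))
    stop("locus_ids must be unique and match the number of columns",
         call. = FALSE)

  bad <- which(!(data %in% c(0, 1) | is.na(data)), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(data))
    stop(sprintf(
      "non-binary band score %s at individual '%s', locus '%s'",
      format(data[bad[1L]]), individual_ids[rc[1L]], locus_ids[rc[2L]]),
      call. = FALSE)
  }
  storage.mode(data) <- "integer"
  dimnames(data) <- list(individual_ids, locus_ids)

  if (is.null(primer_of)) {
    primer_of <- sub(":[^:]*$", "", locus_ids)
    if (any(primer_of == locus_ids))
      stop("locus ids are not of the form 'PRIMER:index'; ",
           "supply primer_of explicitly", call. = FALSE)
  }
  if (length(primer_of) != ncol(data) || anyNA(primer_of))
    stop("every locus must map to exactly one primer", call. = FALSE)
  primer_of <- stats::setNames(as.character(primer_of), locus_ids)

  if (is.null(population_of)) population_of <- rep("pop1", nrow(data))
  if (length(population_of) != nrow(data) || anyNA(population_of))
    stop("every individual must map to exactly one population",
         call. = FALSE)
  population_of <- stats::setNames(
    factor(as.character(population_of),
           levels = unique(as.character(population_of))),
    individual_ids)

  structure(list(data = data, primer_of = primer_of,
                 population_of = population_of),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf(
    "band_matrix: %d individuals x %d loci (%d primers, %d populations)\n",
    nrow(x$data), ncol(x$data), length(unique(x$primer_of)),
    nlevels(x$population_of)))
  nmiss <- sum(is.na(x$data))
  if (nmiss) cat(sprintf("  %d missing scores (%.2f%%)\n", nmiss,
                         100 * nmiss / length(x$data)))
  invisible(x)
}

#' @export
summary.band_matrix <- function(object, ...) {
  print(object)
  cat("  populations:",
      paste(levels(object$population_of), collapse = ", "), "\n")
  invisible(object)
}

#' @export
dim.band_matrix <- function(x) dim(x$data)

n_individuals <- function(m) nrow(m$data)
n_loci <- function(m) ncol(m$data)

#' List the primers of a band matrix
#' @param m a [band_matrix()].
#' @return character vector of primer names in locus order of first
#'   appearance.
#' @export
primers <- function(m) unique(unname(m$primer_of))

loci_of_primer <- function(m, primer) {
  idx <- which(m$primer_of == primer)
  if (!length(idx))
    stop(sprintf("unknown primer '%s'", primer), call. = FALSE)
  idx
}

#' Primer panel metadata
#'
#' Optional descriptive record of the primers behind a band matrix:
#' sequence, annealing temperature and amplified-size range. Purely
#' metadata — no computation consumes the sequences.
#'
#' @param name unique primer names.
#' @param sequence optional primer sequences (5'-3').
#' @param annealing_temp optional annealing temperatures (degrees C).
#' @param size_min,size_max optional amplified-fragment size range (bp),
#'   `size_min <= size_max` where both are present.
#' @return data frame of class `primer_panel`.
#' @export
primer_panel <- function(name, sequence = NULL, annealing_temp = NULL,
                         size_min = NULL, size_max = NULL) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("primer names must be unique", call. = FALSE)
  n <- length(name)
  fill <- function(x, as) if (is.null(x)) rep(as, n) else x
  out <- data.frame(name = name,
                    sequence = fill(sequence, NA_character_),
                    annealing_temp = fill(annealing_temp, NA_real_),
                    size_min = fill(size_min, NA_real_),
                    size_max = fill(size_max, NA_real_))
  bad <- !is.na(out$size_min) & !is.na(out$size_max) &
    out$size_min > out$size_max
  if (any(bad))
    stop("size range lower bound exceeds upper for: ",
         paste(out$name[bad], collapse = ", "), call. = FALSE)
  class(out) <- c("primer_panel", "data.frame")
  out
}

#' Read a band matrix from delimited text
#'
#' Expects individuals as rows and loci as columns, with a header row of
#' locus names of the form `"PRIMER:index"` (or a separate `primer_map`
#' two-column file locus,primer) and the first column holding individual
#' ids. `NA` marks a missing score. A two-column population map file
#' (individual, population) assigns individuals to populations.
#'
#' @param path band matrix file (CSV by default).
#' @param popmap_path optional path to a two-column delimited file with
#'   columns individual, population.
#' @param primer_map_path optional path to a two-column delimited file
#'   with columns locus, primer; overrides the `"PRIMER:index"` parsing.
#' @param sep field separator, default comma.
#' @return a [band_matrix()].
#' @export
read_band_matrix <- function(path, popmap_path = NULL,
                             primer_map_path = NULL, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           row.names = 1L, check.names = FALSE,
                           na.strings = "NA")
  data <- as.matrix(tab)
  pop <- NULL
  if (!is.null(popmap_path)) {
    pm <- utils::read.table(popmap_path, header = TRUE, sep = sep,
                            check.names = FALSE,
                            colClasses = "character")
    idx <- match(rownames(data), pm[[1L]])
    if (anyNA(idx))
      stop("popmap is missing individuals: ",
           paste(rownames(data)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    pop <- pm[[2L]][idx]
  }
  primer <- NULL
  if (!is.null(primer_map_path)) {
    qm <- utils::read.table(primer_map_path, header = TRUE, sep = sep,
                            check.names = FALSE,
                            colClasses = "character")
    idx <- match(colnames(data), qm[[1L]])
    if (anyNA(idx))
      stop("primer map is missing loci: ",
           paste(colnames(data)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    primer <- qm[[2L]][idx]
  }
  band_matrix(data, primer_of = primer, population_of = pop)
}

#' Write a band matrix (and its population map) to delimited text
#'
#' @param m a [band_matrix()].
#' @param path output file for the 0/1 matrix.
#' @param popmap_path optional output file for the individual,population
#'   map.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(m, path, popmap_path = NULL, sep = ",") {
  df <- data.frame(individual = rownames(m$data),
                   m$data, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  if (!is.null(popmap_path)) {
    pm <- data.frame(individual = names(m$population_of),
                     population = as.character(m$population_of))
    utils::write.table(pm, popmap_path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Export a band matrix in STRUCTURE project-data format
#'
#' One row per individual in haploid coding (each band scored as one
#' "allele" column), or two rows per individual in the conventional
#' dominant-diploid recessive coding (band present = genotype 1/-9, band
#' absent = 0/0, unknown phase of the second copy encoded as missing).
#' Missing scores are exported as -9. The first two columns are the
#' individual label and the population as an integer in order of first
#' appearance.
#'
#' @param m a [band_matrix()].
#' @param path output text file.
#' @param coding `"haploid"` (default) or `"dominant-diploid"`.
#' @return `path`, invisibly.
#' @export
export_structure_format <- function(m, path,
                                    coding = c("haploid",
                                               "dominant-diploid")) {
  coding <- match.arg(coding)
  popint <- as.integer(m$population_of)
  x <- m$data
  x[is.na(x)] <- -9L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(m$data), collapse = " "), con)
  for (i in seq_len(nrow(x))) {
    if (coding == "haploid") {
      writeLines(paste(c(rownames(x)[i], popint[i], x[i, ]),
                       collapse = " "), con)
    } else {
      # recessive-allele dominant coding: presence 1/-9 (second copy
      # unobservable), absence 0/0, missing -9/-9
      first <- x[i, ]
      second <- ifelse(first == 1L, -9L, first)
      writeLines(paste(c(rownames(x)[i], popint[i], first),
                       collapse = " "), con)
      writeLines(paste(c(rownames(x)[i], popint[i], second),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Serialize a tree to Newick text
#'
#' @param tree an [ape::phylo] object (as returned by [upgma()] or
#'   [ward_linkage()]).
#' @param path optional file; when `NULL` the Newick string is returned.
#' @param precision significant digits for branch lengths.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL, precision = 10) {
  if (!inherits(tree, "phylo"))
    stop("tree must be a 'phylo' object", call. = FALSE)
  if (is.null(tree$tip.label) || length(tree$tip.label) == 0L)
    stop("empty tree", call. = FALSE)
  txt <- ape::write.tree(tree, digits = precision)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write an analysis result as a delimited table and JSON
#'
#' Produces a deterministic report: fixed column order, floats rounded to
#' a configurable number of decimals, and a versioned JSON mirror of the
#' same table.
#'
#' @param results a data frame produced by this package (per-primer
#'   metrics, diversity tables, Evanno tables, ...).
#' @param path output file stem; `<path>.csv` and `<path>.json` are
#'   written.
#' @param digits decimal places for numeric columns (default 4).
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(results, path, digits = 4) {
  stopifnot(is.data.frame(results))
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.table(out, csv, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(schema = "bandpop-report/1", table = out),
                       json, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = csv, json = json))
}
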
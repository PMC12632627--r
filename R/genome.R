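#' Genome model: chromosome sizes plus a chromosomal-domain map
#'
#' Holds the coordinate system every track in the package lives on: a set of
#' chromosome lengths and a partition of the genome into named chromosomal
#' domains (chromosome arms, pericentromeric heterochromatin blocks,
#' whole chromosomes, and an rDNA repeat-unit contig). All coordinates are
#' 0-based half-open, as in BED.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param regions A data.frame with columns `region_id`, `chrom`, `start`,
#'   `end`, `class`; `class` must be one of `"arm"`, `"pericentromeric"`,
#'   `"whole-chromosome"`, `"rDNA-unit"`. Regions on one chromosome must not
#'   overlap and must lie within the chromosome.
#' @return An object of class `genome_model`: a list with elements
#'   `chrom_sizes` and `regions`.
#' @export
genome_model <- function(chrom_sizes, regions) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  needed <- c("region_id", "chrom", "start", "end", "class")
  if (!all(needed %in% names(regions)))
    stop("regions must have columns: ", paste(needed, collapse = ", "))
  bad_class <- setdiff(unique(regions$class), region_classes())
  if (length(bad_class))
    stop("unknown region class: ", paste(bad_class, collapse = ", "))
  gm <- structure(list(chrom_sizes = chrom_sizes,
                       regions = regions[, needed]),
                  class = "genome_model")
  validate_genome_model(gm)
  gm
}

region_classes <- function() {
  c("arm", "pericentromeric", "whole-chromosome", "rDNA-unit")
}

validate_genome_model <- function(gm) {
  r <- gm$regions
  unknown <- setdiff(r$chrom, names(gm$chrom_sizes))
  if (length(unknown))
    stop("region on unknown chromosome: ", paste(unknown, collapse = ", "))
  if (any(r$start < 0) || any(r$end > gm$chrom_sizes[r$chrom]))
    stop("region coordinates outside chromosome bounds")
  if (any(r$end <= r$start)) stop("region end must exceed start")
  for (ch in unique(r$chrom)) {
    ri <- r[r$chrom == ch, , drop = FALSE]
    ri <- ri[order(ri$start), , drop = FALSE]
    if (nrow(ri) > 1 && any(ri$start[-1] < ri$end[-nrow(ri)]))
      stop("overlapping regions on chromosome ", ch)
  }
  invisible(gm)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_sizes), "chromosomes,",
      format(sum(x$chrom_sizes), big.mark = ","), "bp,",
      nrow(x$regions), "domains\n")
  invisible(x)
}

#' Read a BED file of intervals
#'
#' Minimal BED reader for 3- to 6-column files. Coordinates stay 0-based
#' half-open. Input order is preserved.
#'
#' @param path Path to a tab-separated BED file.
#' @param genome Optional [genome_model()]; when supplied, interval
#'   chromosomes are validated against it.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present in the file, `name`, `score`, `strand`.
#' @export
read_intervals <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  if (any(ends <= starts))
    stop("malformed BED line ", which(ends <= starts)[1], ": end <= start")
  out <- data.frame(chrom = vapply(fields, `[`, "", 1),
                    start = starts, end = ends, stringsAsFactors = FALSE)
  if (any(nf >= 4)) out$name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  if (any(nf >= 5)) out$score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[5] else NA_character_, "")))
  if (any(nf >= 6)) out$strand <- vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", "")
  if (!is.null(genome)) {
    unknown <- setdiff(out$chrom, names(genome$chrom_sizes))
    if (length(unknown))
      stop("interval on unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  out
}

#' Write a per-bin score track as bedGraph
#'
#' Bins must be sorted and non-overlapping within each chromosome. Runs of
#' adjacent bins whose values agree at the written 6-decimal precision are
#' merged into a single line, as genome browsers expect.
#'
#' @param track data.frame with columns `chrom`, `start`, `end` and a value
#'   column (the fourth column, or one named `value`).
#' @param path Output path.
#' @return Invisibly, the number of lines written.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(track)))
  vcol <- if ("value" %in% names(track)) "value" else names(track)[4]
  value <- track[[vcol]]
  keep <- is.finite(value)
  track <- track[keep, , drop = FALSE]
  value <- value[keep]
  for (ch in unique(track$chrom)) {
    i <- track$chrom == ch
    s <- track$start[i]; e <- track$end[i]
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)]))
      stop("bins must be sorted and non-overlapping on chromosome ", ch)
  }
  vstr <- sprintf("%.6f", value)
  # merge runs of touching bins with identical formatted value
  n <- nrow(track)
  if (n == 0) { writeLines(character(), path); return(invisible(0L)) }
  new_run <- c(TRUE, !(track$chrom[-1] == track$chrom[-n] &
                       track$start[-1] == track$end[-n] &
                       vstr[-1] == vstr[-n]))
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, n)
  out <- sprintf("%s\t%d\t%d\t%s", track$chrom[first],
                 as.integer(track$start[first]), as.integer(track$end[last]),
                 vstr[first])
  writeLines(out, path)
  invisible(length(out))
}

#' Read a bedGraph file back into a bin table
#'
#' @param path Path to a 4-column bedGraph file.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  out <- read_intervals(path)
  names(out)[names(out) == "name"] <- "value"
  out$value <- as.numeric(out$value)
  out
}

#' Load a chromosomal-domain configuration
#'
#' Reads a BED-like file with five tab-separated columns: chrom, start, end,
#' region_id, class. The shipped default configuration
#' (`system.file("extdata", "regions_synthetic.bed", package = "replichrom")`)
#' partitions a small synthetic genome into the 12 domains used throughout:
#' four autosomal arms, their four pericentromeric blocks, chromosomes 4, X
#' and Y, and one rDNA repeat unit.
#'
#' @param path Path to the region config file.
#' @param genome Optional [genome_model()] for bounds validation.
#' @return data.frame of regions (`region_id`, `chrom`, `start`, `end`,
#'   `class`).
#' @export
load_region_config <- function(path, genome = NULL) {
  iv <- read_intervals(path)
  if (!all(c("name", "score") %in% names(iv)))
    stop("region config needs 5 columns: chrom, start, end, region_id, class")
  cls <- as.character(iv$score)
  # score slot carried the class string; re-read raw to keep it as text
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character"))
  regions <- data.frame(region_id = raw$V4, chrom = raw$V1,
                        start = raw$V2, end = raw$V3, class = raw$V5,
                        stringsAsFactors = FALSE)
  bad <- setdiff(unique(regions$class), region_classes())
  if (length(bad))
    stop("unknown region class: ", paste(bad, collapse = ", "))
  for (ch in unique(regions$chrom)) {
    ri <- regions[regions$chrom == ch, , drop = FALSE]
    ri <- ri[order(ri$start), , drop = FALSE]
    if (nrow(ri) > 1 && any(ri$start[-1] < ri$end[-nrow(ri)]))
      stop("overlapping regions on chromosome ", ch)
  }
  if (!is.null(genome)) {
    gm <- genome_model(genome$chrom_sizes, regions)
    regions <- gm$regions
  }
  regions
}
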
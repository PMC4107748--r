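#' Construct a CNV genomic region
#'
#' Coordinates follow the UCSC browser display convention: 1-based with
#' both endpoints inclusive, so a region's length is `end - start + 1`.
#' (This convention is pinned by the package's region fixtures, whose
#' published lengths are reproduced exactly under it.)
#'
#' @param cnv_id CNV accession (e.g. `"esv27061"`).
#' @param chrom chromosome name (e.g. `"chr1"`).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param assay_id copy-number assay used to genotype the region.
#' @param snp_id optional tag SNP the region overlaps.
#' @return a `genomic_region` list.
#' @export
genomic_region <- function(cnv_id, chrom, start, end, assay_id = NA_character_,
                           snp_id = NA_character_) {
  stopifnot(is.character(cnv_id), nzchar(cnv_id),
            is.character(chrom), nzchar(chrom))
  if (!is_count(start) || !is_count(end) || start > end || start < 1) {
    stop_ddcnv(sprintf("invalid coordinates %s:%s-%s (need 1 <= start <= end)",
                       chrom, format(start), format(end)),
               "ddcnv_coord_error")
  }
  structure(
    list(cnv_id = cnv_id, chrom = chrom, start = as.numeric(start),
         end = as.numeric(end), assay_id = assay_id, snp_id = snp_id),
    class = "genomic_region"
  )
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("%s  %s:%s-%s  (%s bp, assay %s)\n", x$cnv_id, x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(region_length(x), big.mark = ","), x$assay_id))
  invisible(x)
}

#' Length of a region in base pairs
#'
#' 1-based inclusive: `end - start + 1`. Translation invariant.
#'
#' @param region a [genomic_region()].
#' @return length in bp.
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  region$end - region$start + 1
}

#' Does a SNP position fall inside a region?
#'
#' Inclusive at both endpoints; chromosomes must match (same genome build
#' assumed).
#'
#' @param chrom,position SNP chromosome and 1-based coordinate.
#' @param region a [genomic_region()].
#' @return logical.
#' @export
snp_in_region <- function(chrom, position, region) {
  stopifnot(inherits(region, "genomic_region"), is_count(position))
  identical(chrom, region$chrom) &&
    position >= region$start && position <= region$end
}

# "chr1:112,692,629-113,246,263" -> list(chrom, start, end)
parse_landmark <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1L]]
  if (length(m) != 4L) {
    stop_ddcnv(sprintf("cannot parse genomic landmark '%s'", x),
               "ddcnv_coord_error")
  }
  list(chrom = m[2L],
       start = as.numeric(gsub(",", "", m[3L], fixed = TRUE)),
       end = as.numeric(gsub(",", "", m[4L], fixed = TRUE)))
}

#' Load a CNV region table
#'
#' Reads a tab-separated table with columns `cnv_id`, `chrom`, `start`,
#' `end` and optionally `assay_id` and `snp_id` (or a `landmark` column in
#' `chrom:start-end` form instead of the three coordinate columns).
#' Comma-grouped digits are accepted. Coordinate invariants are enforced
#' on every row. The package ships the regions it models in
#' `system.file("extdata", "cnv_regions.tsv", package = "ddcnv")`.
#'
#' @param path file path, or `NULL` (default) for the shipped region table.
#' @return list of `genomic_region` objects (possibly empty), named by
#'   `cnv_id`.
#' @export
load_region_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cnv_regions.tsv", package = "ddcnv")
  }
  if (!file.exists(path)) {
    stop_ddcnv(sprintf("region table not found: %s", path), "ddcnv_io_error")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  if ("landmark" %in% names(tab) && !all(c("start", "end") %in% names(tab))) {
    parsed <- lapply(tab$landmark, parse_landmark)
    tab$chrom <- vapply(parsed, `[[`, character(1), "chrom")
    tab$start <- vapply(parsed, `[[`, numeric(1), "start")
    tab$end <- vapply(parsed, `[[`, numeric(1), "end")
  }
  need <- c("cnv_id", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    stop_ddcnv("region table needs columns cnv_id, chrom, start, end (or landmark)",
               "ddcnv_io_error")
  }
  num <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))
  regions <- lapply(seq_len(nrow(tab)), function(i) {
    genomic_region(
      cnv_id = tab$cnv_id[i], chrom = tab$chrom[i],
      start = num(tab$start[i]), end = num(tab$end[i]),
      assay_id = if ("assay_id" %in% names(tab)) tab$assay_id[i] else NA_character_,
      snp_id = if ("snp_id" %in% names(tab)) tab$snp_id[i] else NA_character_
    )
  })
  names(regions) <- tab$cnv_id
  regions
}

#' Export regions as BED
#'
#' Converts from the package's 1-based inclusive coordinates to BED's
#' 0-based half-open convention (`chromStart = start - 1`,
#' `chromEnd = end`).
#'
#' @param regions list of `genomic_region` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(vapply(regions, inherits, logical(1), "genomic_region")))
  bed <- data.frame(
    chrom = vapply(regions, `[[`, character(1), "chrom"),
    chromStart = vapply(regions, `[[`, numeric(1), "start") - 1,
    chromEnd = vapply(regions, `[[`, numeric(1), "end"),
    name = vapply(regions, `[[`, character(1), "cnv_id")
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
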
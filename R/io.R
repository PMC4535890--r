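# Readers/writers for the pipeline's delimited-text dialects, the
# samples-by-markers call/intensity containers, genome metadata and BED
# export.  Internal coordinates are 1-based closed throughout; only
# write_bed()/read_bed() convert to/from the 0-based half-open convention.

# canonical chromosome rank: chr1 < chr2 < ... < chr22 < chrX (no Y/MT in
# this pipeline); unknown names sort after, alphabetically
chrom_rank <- function(chrom) {
  canon <- c(paste0("chr", 1:22), "chrX")
  r <- match(chrom, canon)
  extra <- sort(unique(chrom[is.na(r)]))
  r[is.na(r)] <- length(canon) + match(chrom[is.na(r)], extra)
  r
}

#' Read a per-platform marker annotation table
#'
#' The annotation maps each array marker to a genome position and, for SNP
#' probes, its two alleles on the annotated strand.  Intensity-only probes
#' (copy-number probes) carry empty allele fields.  Markers are returned
#' sorted by `(chrom, pos)` with ties broken by `marker_id`, which is the
#' ordering every downstream stage assumes.
#'
#' Duplicate `(chrom, pos)` entries are accepted here — arrays do ship
#' probes duplicated at one position — and are dealt with during haploid QC
#' ([remove_duplicate_position_markers()]).  Duplicate `marker_id`s are an
#' error.
#'
#' @param path Tab-delimited file with header columns `marker_id`, `chrom`,
#'   `pos`, `allele_a`, `allele_b`, `probe_class`.
#' @param platform Platform label, `"A"` or `"B"`.
#' @return A tibble with columns `marker_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `probe_class`, `platform`, sorted by position.
#' @export
read_marker_annotation <- function(path, platform = c("A", "B")) {
  platform <- match.arg(platform)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("marker_id", "chrom", "pos", "allele_a", "allele_b", "probe_class")
  if (!all(need %in% names(df))) {
    stop("annotation file lacks columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  line_no <- seq_len(nrow(df)) + 1L  # +1 for header
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop("malformed position '", df$pos[bad[1]], "' at line ", line_no[bad[1]])
  }
  bad <- which(!df$probe_class %in% c("snp", "intensity_only"))
  if (length(bad)) {
    stop("unknown probe_class '", df$probe_class[bad[1]], "' at line ", line_no[bad[1]])
  }
  dup <- which(duplicated(df$marker_id))
  if (length(dup)) {
    stop("duplicate marker_id '", df$marker_id[dup[1]], "' at line ", line_no[dup[1]])
  }
  is_snp <- df$probe_class == "snp"
  bad <- which(is_snp & (!df$allele_a %in% c("A", "C", "G", "T") |
                         !df$allele_b %in% c("A", "C", "G", "T") |
                         df$allele_a == df$allele_b))
  if (length(bad)) {
    stop("invalid alleles '", df$allele_a[bad[1]], "/", df$allele_b[bad[1]],
         "' for snp probe at line ", line_no[bad[1]])
  }
  ann <- tibble::tibble(
    marker_id = df$marker_id, chrom = df$chrom, pos = pos,
    allele_a = ifelse(is_snp, df$allele_a, ""),
    allele_b = ifelse(is_snp, df$allele_b, ""),
    probe_class = df$probe_class, platform = platform
  )
  sort_annotation(ann)
}

sort_annotation <- function(ann) {
  ann[order(chrom_rank(ann$chrom), ann$pos, ann$marker_id), , drop = FALSE]
}

#' @rdname read_marker_annotation
#' @param ann Annotation tibble as returned by [read_marker_annotation()].
#' @export
write_marker_annotation <- function(ann, path) {
  utils::write.table(
    ann[, c("marker_id", "chrom", "pos", "allele_a", "allele_b", "probe_class")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

new_chm_matrix <- function(m, class) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  structure(m, class = c(class, class(m)))
}

#' Genotype-call and intensity containers
#'
#' `genotype_matrix()` wraps a samples-by-markers character matrix of calls
#' over the haploid-array alphabet `AA`/`BB`/`AB`/`NC` (homozygous allele a,
#' homozygous allele b, heterozygous, no-call).  `intensity_matrix()` wraps
#' a numeric matrix of relative signal intensities on the log2-ratio scale
#' (log2R for platform A, logRR for platform B); `NA` marks a missing value.
#' Row names are sample ids, column names marker ids.
#'
#' @param calls Character matrix of genotype codes.
#' @return A `chm_calls` or `chm_intens` object (a classed matrix).
#' @export
genotype_matrix <- function(calls) {
  bad <- setdiff(unique(as.vector(calls)), GENO_CODES)
  if (length(bad)) stop("unknown genotype token '", bad[1], "'")
  new_chm_matrix(calls, "chm_calls")
}

#' @rdname genotype_matrix
#' @param values Numeric matrix of intensities (NA = missing).
#' @export
intensity_matrix <- function(values) {
  storage.mode(values) <- "double"
  new_chm_matrix(values, "chm_intens")
}

#' @export
print.chm_calls <- function(x, ...) {
  cat("<chm_calls> ", nrow(x), " samples x ", ncol(x), " markers; ",
      "call rate ", sprintf("%.4f", mean(x != "NC")), "\n", sep = "")
  invisible(x)
}

#' @export
print.chm_intens <- function(x, ...) {
  cat("<chm_intens> ", nrow(x), " samples x ", ncol(x), " markers; ",
      sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

#' Read a samples-by-markers call or intensity matrix
#'
#' The file is tab-delimited: first column `sample_id`, one column per
#' marker.  Genotype files use codes `AA`, `BB`, `AB`, `NC`; any other token
#' is an error.  Blank intensity cells become missing values.
#'
#' @param path File path.
#' @param kind `"genotype"` or `"intensity"`.
#' @return A [genotype_matrix()] or [intensity_matrix()].
#' @export
read_matrix <- function(path, kind = c("genotype", "intensity")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # a trailing empty cell is dropped by strsplit; pad ragged-at-end rows
  ncol_hdr <- length(fields[[1]])
  fields[-1] <- lapply(fields[-1], function(f) {
    if (length(f) == ncol_hdr - 1L) c(f, "") else f
  })
  nc <- lengths(fields[-1])
  if (any(nc != ncol_hdr)) {
    stop("ragged row at line ", which(nc != ncol_hdr)[1] + 1L)
  }
  header <- fields[[1]]
  markers <- header[-1]
  body <- fields[-1]
  samples <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(samples)) {
    stop("duplicated sample id '", samples[duplicated(samples)][1], "'")
  }
  cells <- matrix(unlist(lapply(body, `[`, -1L)), nrow = length(body),
                  byrow = TRUE, dimnames = list(samples, markers))
  if (kind == "genotype") {
    genotype_matrix(cells)
  } else {
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                   dimnames = dimnames(cells)))
    bad <- cells != "" & !is.na(cells) & is.na(vals)
    if (any(bad)) stop("non-numeric intensity cell '", cells[bad][1], "'")
    intensity_matrix(vals)
  }
}

#' @rdname read_matrix
#' @param x A `chm_calls` or `chm_intens` object.
#' @export
write_matrix <- function(x, path) {
  m <- unclass(x)
  if (is.numeric(m)) {
    m2 <- matrix(ifelse(is.na(m), "", format(m, trim = TRUE, digits = 15,
                                             scientific = FALSE)),
                 nrow = nrow(m), dimnames = dimnames(m))
    m <- m2
  }
  out <- cbind(sample_id = rownames(m), m)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genome metadata: chromosome lengths and centromere intervals
#'
#' @param path Tab-delimited file with columns `chrom`, `length_bp`,
#'   `centromere_start`, `centromere_end` (1-based closed interval).
#' @return A tibble, one row per chromosome.
#' @export
read_genome_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", rep("integer", 3)))
  gm <- tibble::as_tibble(df[, c("chrom", "length_bp", "centromere_start",
                                 "centromere_end")])
  validate_genome_metadata(gm)
}

validate_genome_metadata <- function(gm) {
  ok <- gm$centromere_start >= 1 & gm$centromere_end <= gm$length_bp &
    gm$centromere_start <= gm$centromere_end
  if (!all(ok)) {
    stop("centromere interval outside [1, length] for ", gm$chrom[!ok][1])
  }
  gm[order(chrom_rank(gm$chrom)), , drop = FALSE]
}

#' @rdname read_genome_metadata
#' @param gm Genome-metadata tibble.
#' @export
write_genome_metadata <- function(gm, path) {
  utils::write.table(gm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED
#'
#' Internal intervals are 1-based closed; BED is 0-based half-open, so the
#' written start is `start - 1` and the written end is `end`.  Lines are
#' sorted by `(chrom, start)`.
#'
#' @param intervals Tibble/data frame with columns `chrom`, `start`, `end`
#'   and optionally `name`, `score` plus any extra columns.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  iv <- tibble::as_tibble(intervals)
  if (any(iv$end < iv$start)) {
    bad <- which(iv$end < iv$start)[1]
    stop("interval end < start: ", iv$chrom[bad], ":", iv$start[bad], "-", iv$end[bad])
  }
  if (!"name" %in% names(iv)) iv$name <- "."
  if (!"score" %in% names(iv)) iv$score <- 0
  iv <- iv[order(chrom_rank(iv$chrom), iv$start, iv$end), , drop = FALSE]
  extra <- setdiff(names(iv), c("chrom", "start", "end", "name", "score"))
  out <- data.frame(chrom = iv$chrom, start = iv$start - 1L, end = iv$end,
                    name = iv$name, score = iv$score,
                    iv[, extra, drop = FALSE], check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @return `read_bed()` returns a tibble with 1-based closed `start`/`end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  tibble::tibble(
    chrom = df[[1]],
    start = as.integer(df[[2]]) + 1L,
    end = as.integer(df[[3]]),
    name = if (ncol(df) >= 4) df[[4]] else ".",
    score = if (ncol(df) >= 5) as.numeric(df[[5]]) else 0
  )
}

#' @export
tidy.chm_calls <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    marker_id = rep(colnames(x), each = nrow(x)),
    call = as.vector(unclass(x))
  )
}

#' @export
tidy.chm_intens <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    marker_id = rep(colnames(x), each = nrow(x)),
    intensity = as.vector(unclass(x))
  )
}
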
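# Readers and writers for the external formats: per-region depth-threshold
# count tables ("covdata"), target BEDs, per-base depth tracks, and the
# output BED / browser-track files. Coordinates are BED convention
# throughout: 0-based, half-open, so region length = end - start.

DEPTH_COL_RE <- "^([0-9]+)[xX]$"
WIDE_COL_RE <- "^(.*)_([0-9]+)[xX]$"

#' Extract the gene symbol from a region identifier
#'
#' Region identifiers on targeted panels commonly encode the gene as a
#' prefix, e.g. `"BRCA1_exon24"`. The gene symbol is taken as everything
#' before the first occurrence of `separator`; an identifier without the
#' separator is returned unchanged.
#'
#' @param region_id Character vector of region identifiers.
#' @param separator Literal separator string (default `"_"`).
#' @return Character vector of gene symbols, same length as `region_id`.
#' @examples
#' parse_gene(c("BRCA1_exon24", "TP53", "EGFR_ex19_del"))
#' @export
parse_gene <- function(region_id, separator = "_") {
  region_id <- as.character(region_id)
  pos <- regexpr(separator, region_id, fixed = TRUE)
  ifelse(pos > 0L, substr(region_id, 1L, pos - 1L), region_id)
}

region_key <- function(regions) {
  paste(regions$chrom, regions$start, regions$end, regions$region_id,
        sep = "\r")
}

validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions))
  need <- c("chrom", "start", "end", "region_id")
  miss <- setdiff(need, names(regions))
  if (length(miss) > 0) {
    stop("region table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(regions) == 0) return(invisible(regions))
  if (any(!nzchar(regions$chrom))) stop("empty chromosome name in region table")
  bad <- regions$end <= regions$start
  if (any(bad)) {
    stop("region(s) with end <= start: ",
         paste(regions$region_id[bad], collapse = ", "))
  }
  invisible(regions)
}

#' Construct a per-region depth-threshold count table
#'
#' The central input container: for each target region (exon), each sample
#' and each depth threshold, the number of bases of the region covered at
#' or above that depth. Counts must not exceed the region length and must
#' be non-increasing in depth (a base covered at 500X is covered at 250X).
#'
#' @param regions Data frame with columns `chrom`, `start`, `end`,
#'   `region_id` and optionally `gene` (derived with [parse_gene()] when
#'   absent). Coordinates are 0-based half-open.
#' @param depths Integer vector of depth thresholds (X-fold); stored in
#'   ascending order.
#' @param counts Numeric array of dimension `n_regions x n_depths x
#'   n_samples`, in the order of `regions`, `depths`, `samples`.
#' @param samples Character vector of sample identifiers.
#' @param lenient If `TRUE`, depth-monotonicity violations raise a warning
#'   instead of an error.
#' @return An object of class `covdata`.
#' @export
covdata <- function(regions, depths, counts, samples, lenient = FALSE) {
  validate_regions(regions)
  if (!"gene" %in% names(regions)) regions$gene <- parse_gene(regions$region_id)
  depths <- as.integer(depths)
  if (is.unsorted(depths, strictly = TRUE)) {
    ord <- order(depths)
    depths <- depths[ord]
    counts <- counts[, ord, , drop = FALSE]
    if (anyDuplicated(depths)) stop("duplicated depth thresholds")
  }
  samples <- as.character(samples)
  counts <- array(as.numeric(counts),
                  dim = c(nrow(regions), length(depths), length(samples)),
                  dimnames = list(region_key(regions), as.character(depths),
                                  samples))
  if (nrow(regions) > 0) {
    if (anyDuplicated(region_key(regions))) {
      stop("duplicated region key (chrom, start, end, region_id)")
    }
    if (any(counts < 0)) stop("negative coverage count")
    len <- regions$end - regions$start
    over <- which(sweep(counts, 1, len, ">"), arr.ind = TRUE)
    if (nrow(over) > 0) {
      i <- over[1, ]
      stop(sprintf("count exceeds region length for region '%s', sample '%s'",
                   regions$region_id[i[1]], samples[i[3]]))
    }
    if (length(depths) > 1) {
      nd <- length(depths)
      viol <- counts[, -1, , drop = FALSE] > counts[, -nd, , drop = FALSE]
      if (any(viol)) {
        i <- which(viol, arr.ind = TRUE)[1, ]
        msg <- sprintf(
          "counts increase with depth for region '%s', sample '%s'",
          regions$region_id[i[1]], samples[i[3]])
        if (lenient) warning(msg) else stop(msg)
      }
    }
  }
  structure(list(regions = regions, depths = depths, samples = samples,
                 counts = counts),
            class = "covdata")
}

#' @export
print.covdata <- function(x, ...) {
  cat(sprintf("covdata: %d regions x %d depths (%s) x %d samples\n",
              nrow(x$regions), length(x$depths),
              paste0(x$depths, "X", collapse = ","), length(x$samples)))
  invisible(x)
}

read_tsv_raw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
}

normalize_covdata_names <- function(nm) {
  low <- tolower(nm)
  nm[low %in% c("chrom", "chromosome", "chr", "#chrom")] <- "chrom"
  nm[low %in% c("start", "region_start")] <- "start"
  nm[low %in% c("end", "region_end")] <- "end"
  nm[low %in% c("region", "region_id", "name", "id")] <- "region_id"
  nm
}

#' Read a covdata table
#'
#' Two dialects are supported and auto-detected from the header:
#' `"per_sample"` (one file per sample with plain depth columns such as
#' `5X`, `10X`, ... ; pass several paths for several samples) and
#' `"wide"` (a single file with sample-prefixed depth columns such as
#' `S01_100X`). Mandatory columns are `chrom`, `start`, `end` and
#' `region`/`region_id`; depth columns are parsed case-insensitively from
#' `<n>X` and returned in ascending depth order regardless of file order.
#'
#' @param path Path to a covdata TSV, or a vector of paths (one per
#'   sample) for the per-sample dialect.
#' @param dialect `"auto"` (default), `"per_sample"` or `"wide"`.
#' @param samples Optional sample names; defaults to file basenames
#'   (per-sample) or the column prefixes (wide).
#' @param lenient Passed to [covdata()]: downgrade depth-monotonicity
#'   violations to warnings.
#' @param gene_separator Separator used by [parse_gene()].
#' @return A [covdata()] object.
#' @export
read_covdata <- function(path, dialect = c("auto", "per_sample", "wide"),
                         samples = NULL, lenient = FALSE,
                         gene_separator = "_") {
  dialect <- match.arg(dialect)
  for (p in path) if (!file.exists(p)) stop("file not found: ", p)
  first <- read_tsv_raw(path[1])
  names(first) <- normalize_covdata_names(names(first))
  extra <- setdiff(names(first), c("chrom", "start", "end", "region_id"))
  plain <- grepl(DEPTH_COL_RE, extra)
  widec <- grepl(WIDE_COL_RE, extra)
  if (dialect == "auto") {
    dialect <- if (length(path) > 1 || (any(plain) && !any(widec & !plain))) {
      "per_sample"
    } else if (any(widec)) "wide" else "per_sample"
  }
  need <- c("chrom", "start", "end", "region_id")
  miss <- setdiff(need, names(first))
  if (length(miss) > 0) {
    stop("covdata file ", path[1], " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }

  if (dialect == "wide") {
    if (length(path) != 1) stop("wide dialect expects a single file")
    dcols <- extra[grepl(WIDE_COL_RE, extra)]
    if (length(dcols) == 0) {
      stop("covdata file ", path, " has no '<sample>_<n>X' depth columns")
    }
    smp <- sub(WIDE_COL_RE, "\\1", dcols)
    dep <- as.integer(sub(WIDE_COL_RE, "\\2", dcols))
    samples_out <- unique(smp)
    depths <- sort(unique(dep))
    regions <- first[, need]
    regions$gene <- parse_gene(regions$region_id, gene_separator)
    counts <- array(NA_real_, dim = c(nrow(regions), length(depths),
                                      length(samples_out)))
    for (k in seq_along(dcols)) {
      counts[, match(dep[k], depths), match(smp[k], samples_out)] <-
        as.numeric(first[[dcols[k]]])
    }
    if (anyNA(counts) && nrow(regions) > 0) {
      stop("incomplete sample x depth column grid in wide covdata file")
    }
    return(covdata(regions, depths, counts, samples_out, lenient = lenient))
  }

  # per-sample dialect: one file per sample, plain "<n>X" depth columns
  if (is.null(samples)) {
    samples <- sub("\\.(tsv|txt|covdata)$", "", basename(path))
  }
  tabs <- vector("list", length(path))
  for (i in seq_along(path)) {
    tb <- if (i == 1) first else read_tsv_raw(path[i])
    names(tb) <- normalize_covdata_names(names(tb))
    miss <- setdiff(need, names(tb))
    if (length(miss) > 0) {
      stop("covdata file ", path[i], " is missing mandatory column(s): ",
           paste(miss, collapse = ", "))
    }
    tabs[[i]] <- tb
  }
  dcols <- names(tabs[[1]])[grepl(DEPTH_COL_RE, names(tabs[[1]]))]
  if (length(dcols) == 0) {
    stop("covdata file ", path[1], " has no '<n>X' depth columns")
  }
  depths <- as.integer(sub(DEPTH_COL_RE, "\\1", dcols))
  ord <- order(depths)
  dcols <- dcols[ord]
  depths <- depths[ord]
  regions <- tabs[[1]][, need]
  regions$gene <- parse_gene(regions$region_id, gene_separator)
  key0 <- region_key(regions)
  if (anyDuplicated(key0)) {
    stop("duplicated region key within covdata file ", path[1])
  }
  counts <- array(NA_real_, dim = c(nrow(regions), length(depths),
                                    length(samples)))
  for (i in seq_along(tabs)) {
    tb <- tabs[[i]]
    ki <- paste(tb$chrom, tb$start, tb$end, tb$region_id, sep = "\r")
    if (anyDuplicated(ki)) {
      stop("duplicated region key within covdata file ", path[i])
    }
    if (nrow(tb) != nrow(regions) || !setequal(ki, key0)) {
      stop("region set in ", path[i], " does not match ", path[1])
    }
    m <- match(key0, ki)
    for (j in seq_along(dcols)) {
      if (!dcols[j] %in% names(tb)) {
        stop("covdata file ", path[i], " is missing depth column ", dcols[j])
      }
      counts[, j, i] <- as.numeric(tb[[dcols[j]]][m])
    }
  }
  covdata(regions, depths, counts, samples, lenient = lenient)
}

#' Write a covdata table
#'
#' @param x A [covdata()] object.
#' @param path Output file (wide dialect) or directory (per-sample
#'   dialect, one `<sample>.tsv` per sample).
#' @param dialect `"wide"` or `"per_sample"`.
#' @return Invisibly, the path(s) written.
#' @export
write_covdata <- function(x, path, dialect = c("wide", "per_sample")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "covdata"))
  base <- x$regions[, c("chrom", "start", "end", "region_id")]
  names(base)[4] <- "region"
  if (dialect == "wide") {
    out <- base
    for (s in seq_along(x$samples)) {
      for (d in seq_along(x$depths)) {
        out[[paste0(x$samples[s], "_", x$depths[d], "X")]] <- x$counts[, d, s]
      }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  paths <- character(length(x$samples))
  for (s in seq_along(x$samples)) {
    out <- base
    for (d in seq_along(x$depths)) {
      out[[paste0(x$depths[d], "X")]] <- x$counts[, d, s]
    }
    paths[s] <- file.path(path, paste0(x$samples[s], ".tsv"))
    utils::write.table(out, paths[s], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Read a BED file of target regions
#'
#' Plain BED (0-based half-open), at least 3 columns; column 4 becomes
#' `region_id` when present, column 5 `score`. `track`/`browser`/comment
#' lines are skipped.
#'
#' @param path BED file path.
#' @param gene_separator Separator for [parse_gene()].
#' @return Data frame with columns `chrom`, `start`, `end`, `region_id`,
#'   `gene` (and `score` when present).
#' @export
read_bed <- function(path, gene_separator = "_") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), region_id = character(),
                      gene = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  if (ncol < 3) stop("BED file ", path, " has fewer than 3 columns")
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  df$region_id <- if (ncol >= 4) vapply(fields, `[[`, "", 4L) else
    paste0(df$chrom, ":", df$start, "-", df$end)
  if (ncol >= 5) df$score <- as.numeric(vapply(fields, `[[`, "", 5L))
  df$gene <- parse_gene(df$region_id, gene_separator)
  validate_regions(df)
  df
}

format_bed_lines <- function(records) {
  cols <- list(records$chrom, records$start, records$end)
  if (!is.null(records$name)) {
    cols <- c(cols, list(records$name))
    if (!is.null(records$score)) cols <- c(cols, list(records$score))
  } else if (!is.null(records$region_id)) {
    cols <- c(cols, list(records$region_id))
    if (!is.null(records$score)) cols <- c(cols, list(records$score))
  }
  do.call(paste, c(cols, sep = "\t"))
}

check_bed_sorted <- function(records, auto_sort) {
  if (nrow(records) == 0) return(records)
  ord <- order(records$chrom, records$start, records$end)
  if (!identical(ord, seq_len(nrow(records)))) {
    if (!auto_sort) stop("BED records are not sorted by (chrom, start); ",
                         "use auto_sort = TRUE to sort on output")
    records <- records[ord, , drop = FALSE]
  }
  if (!is.null(records$score)) {
    s <- records$score[!is.na(records$score)]
    if (length(s) > 0 && (any(s < 0) || any(s > 1000))) {
      stop("BED score outside [0, 1000]")
    }
  }
  records
}

#' Write records as a BED file
#'
#' Standard BED: 0-based half-open coordinates, tab-separated, no header.
#' Records must arrive sorted by `(chrom, start)` unless `auto_sort` is
#' set. Optional columns `name` (or `region_id`) and `score` (0-1000)
#' yield BED4/BED5.
#'
#' @param records Data frame with `chrom`, `start`, `end` and optional
#'   `name`/`region_id`, `score` columns.
#' @param path Output path.
#' @param auto_sort Sort records instead of failing on unsorted input.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(records, path, auto_sort = FALSE) {
  records <- check_bed_sorted(records, auto_sort)
  writeLines(format_bed_lines(records), path)
  invisible(path)
}

#' Write records as a Genome Browser track file
#'
#' Identical to [write_bed()] but preceded by a single `track` declaration
#' line carrying the track name and description, so the file can be loaded
#' directly into a genome browser.
#'
#' @inheritParams write_bed
#' @param track_name Track name (quoted into the declaration line).
#' @param description Track description; defaults to the name.
#' @export
write_track <- function(records, path, track_name,
                        description = track_name, auto_sort = FALSE) {
  records <- check_bed_sorted(records, auto_sort)
  header <- sprintf('track name="%s" description="%s"', track_name,
                    description)
  writeLines(c(header, format_bed_lines(records)), path)
  invisible(path)
}

#' Construct a per-base depth profile for one region and sample
#'
#' @param chrom,start,end Region coordinates (0-based half-open).
#' @param region_id Region identifier.
#' @param sample Sample identifier.
#' @param depth Integer vector of per-base depths, length `end - start`.
#' @param gene Gene symbol; parsed from `region_id` when missing.
#' @return An object of class `perbase_profile`.
#' @export
perbase_profile <- function(chrom, start, end, region_id, sample, depth,
                            gene = parse_gene(region_id)) {
  if (length(depth) != end - start) {
    stop("depth array length (", length(depth),
         ") does not equal region length (", end - start, ")")
  }
  if (any(depth < 0)) stop("negative per-base depth")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), region_id = region_id, gene = gene,
                 sample = sample, depth = as.integer(depth)),
            class = "perbase_profile")
}

#' Read a run-length encoded per-base depth track
#'
#' The input is a BED-like 4-column file (`chrom`, `start`, `end`,
#' `depth`) with run-length encoded depths, as produced by standard depth
#' counters, for one sample. Depth arrays are materialised per target
#' region by intersection; bases with no record get depth 0. Overlapping
#' run-length records are rejected.
#'
#' @param path Path to the 4-column depth file (no header).
#' @param targets Target regions: a data frame as returned by
#'   [read_bed()], or a path to a BED file.
#' @param sample Sample identifier attached to the profiles.
#' @return A list of [perbase_profile()] objects, one per target region.
#' @export
read_perbase <- function(path, targets, sample = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(targets)) targets <- read_bed(targets)
  validate_regions(targets)
  rec <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "depth"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
  for (ch in unique(rec$chrom)) {
    r <- rec[rec$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)])) {
      stop("overlapping run-length depth records on ", ch)
    }
  }
  lapply(seq_len(nrow(targets)), function(i) {
    t0 <- targets$start[i]; t1 <- targets$end[i]
    depth <- integer(t1 - t0)
    hit <- rec[rec$chrom == targets$chrom[i] & rec$start < t1 &
                 rec$end > t0, , drop = FALSE]
    for (j in seq_len(nrow(hit))) {
      s <- max(hit$start[j], t0); e <- min(hit$end[j], t1)
      depth[(s - t0 + 1L):(e - t0)] <- hit$depth[j]
    }
    perbase_profile(targets$chrom[i], t0, t1, targets$region_id[i], sample,
                    depth)
  })
}

#' Write per-base profiles as a run-length encoded depth track
#'
#' Inverse of [read_perbase()] for profiles over disjoint regions: each
#' profile's depth array is run-length encoded into `chrom start end
#' depth` records.
#'
#' @param profiles A list of [perbase_profile()] objects (one sample).
#' @param path Output path.
#' @export
write_perbase <- function(profiles, path) {
  if (inherits(profiles, "perbase_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(pr) {
    r <- rle(pr$depth)
    ends <- cumsum(r$lengths)
    data.frame(chrom = pr$chrom, start = pr$start + ends - r$lengths,
               end = pr$start + ends, depth = r$values,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$depth > 0, , drop = FALSE]  # absent record means depth 0
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
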
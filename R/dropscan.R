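# Base-level coverage-drop detection: narrow runs of low depth inside
# otherwise well-covered exons. Such drops can hide false-negative
# variant calls in regions that look covered at the region level.

empty_drops <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             region_id = character(), gene = character(),
             sample = character(), width = integer(),
             exon_median_depth = numeric(), drop_median_depth = numeric(),
             ratio = numeric(), stringsAsFactors = FALSE)
}

#' Detect narrow coverage drops within well-covered exons
#'
#' An exon is eligible when its per-base median depth reaches
#' `eligibility_depth`. Within an eligible exon, a drop is a maximal run
#' of at least `min_width` consecutive bases whose depth is strictly
#' below `drop_ratio` times the exon's median depth; runs separated by at
#' least one passing base are distinct drops. Drops are clipped at exon
#' boundaries, so boundary decay outside the exon never registers.
#'
#' The drop criterion parameters are this tool's operational definition
#' of "narrow drop inside a highly covered exon"; all three are
#' configurable.
#'
#' @param profiles A [perbase_profile()] or list of them.
#' @param min_width Minimum drop width in bases (default 10).
#' @param drop_ratio Depth ratio defining "low" relative to the exon
#'   median, in (0, 1) (default 0.5).
#' @param eligibility_depth Minimum exon median depth (X-fold) for the
#'   exon to be scanned at all (default 100).
#' @return Data frame of drops sorted by coordinate: `chrom`, `start`,
#'   `end`, `region_id`, `gene`, `sample`, `width`, `exon_median_depth`,
#'   `drop_median_depth`, `ratio`. Zero rows when nothing is found.
#' @export
detect_drops <- function(profiles, min_width = 10, drop_ratio = 0.5,
                         eligibility_depth = 100) {
  if (inherits(profiles, "perbase_profile")) profiles <- list(profiles)
  stopifnot(min_width >= 1, drop_ratio > 0, drop_ratio < 1)
  out <- lapply(profiles, function(pr) {
    if (length(pr$depth) == 0) {
      stop("empty per-base profile for region ", pr$region_id)
    }
    med <- stats::median(pr$depth)
    if (med < eligibility_depth) return(NULL)
    low <- pr$depth < drop_ratio * med
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_width)
    if (length(keep) == 0) return(NULL)
    dmed <- vapply(keep, function(i) {
      stats::median(pr$depth[starts[i]:ends[i]])
    }, 0)
    data.frame(chrom = pr$chrom,
               start = pr$start + starts[keep] - 1L,
               end = pr$start + ends[keep],
               region_id = pr$region_id, gene = pr$gene,
               sample = pr$sample, width = r$lengths[keep],
               exon_median_depth = med, drop_median_depth = dmed,
               ratio = dmed / med, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) return(empty_drops())
  drops <- do.call(rbind, out)
  drops <- drops[order(drops$chrom, drops$start, drops$end, drops$sample), ,
                 drop = FALSE]
  rownames(drops) <- NULL
  drops
}

#' Aggregate coverage drops per gene
#'
#' @param drops Data frame from [detect_drops()].
#' @return Data frame `gene`, `n_drops`, `total_bp`, `affected_exons`,
#'   `samples_affected`, sorted by `total_bp` descending.
#' @export
aggregate_gene_drops <- function(drops) {
  if (nrow(drops) == 0) {
    return(data.frame(gene = character(), n_drops = integer(),
                      total_bp = integer(), affected_exons = integer(),
                      samples_affected = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(drops, drops$gene)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(gene = g$gene[1], n_drops = nrow(g),
               total_bp = sum(g$width),
               affected_exons = length(unique(g$region_id)),
               samples_affected = length(unique(g$sample)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_bp, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export drop results: BED, gene-level table and browser track
#'
#' Writes `drops.bed` (name = `gene:region_id:sample`, score =
#' `round(1000 * (1 - ratio))`), `gene_drops.tsv` and `drops.track.bed`.
#'
#' @param drops Data frame from [detect_drops()].
#' @param summaries Data frame from [aggregate_gene_drops()]; recomputed
#'   when `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param track_name Name written into the track declaration line.
#' @return Invisibly, the three paths written.
#' @export
export_drops <- function(drops, summaries = NULL, out_dir,
                         track_name = "coverage_drops") {
  if (is.null(summaries)) summaries <- aggregate_gene_drops(drops)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rec <- data.frame(chrom = drops$chrom, start = drops$start,
                    end = drops$end,
                    name = paste(drops$gene, drops$region_id, drops$sample,
                                 sep = ":"),
                    score = pmin(1000, pmax(0, round(1000 * (1 - drops$ratio)))),
                    stringsAsFactors = FALSE)
  if (nrow(rec) == 0) rec <- rec[0, , drop = FALSE]
  bed <- file.path(out_dir, "drops.bed")
  tsv <- file.path(out_dir, "gene_drops.tsv")
  trk <- file.path(out_dir, "drops.track.bed")
  write_bed(rec, bed, auto_sort = TRUE)
  utils::write.table(summaries, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_track(rec, trk, track_name = track_name,
              description = "narrow coverage drops in covered exons",
              auto_sort = TRUE)
  invisible(c(bed, tsv, trk))
}
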
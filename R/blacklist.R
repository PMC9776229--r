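# Region blacklisting: exons whose cohort MPC falls below the
# reliability rule at a given depth are written out per depth as BED
# files, since such exons may harbour false-negative variant calls.

#' Blacklist regions with unreliable coverage
#'
#' A region is blacklisted at depth `D` when its MPC at `D` is strictly
#' below the threshold (a region at exactly the threshold is kept,
#' consistent with the inclusive ">= 75%" quality rule). Blacklisting
#' uses the cohort MPC; per-sample depletion is reported separately by
#' [flag_depleted_samples()].
#'
#' @param profile An `mpc_profile` from [mpc()].
#' @param grid Depth thresholds to evaluate (default: all in profile).
#' @param threshold Blacklist threshold in percent (default 75).
#' @return Named list (one element per depth, name `"<d>X"`) of data
#'   frames with columns `chrom`, `start`, `end`, `region_id`, `gene`,
#'   `depth`, `mpc`, `reason`, sorted by coordinate.
#' @export
blacklist_regions <- function(profile, grid = attr(profile, "depths"),
                              threshold = 75) {
  stopifnot(inherits(profile, "mpc_profile"))
  depths <- attr(profile, "depths")
  regions <- attr(profile, "regions")
  grid <- as.integer(grid)
  if (!all(grid %in% depths)) {
    stop("grid depth(s) not present in the MPC profile: ",
         paste(setdiff(grid, depths), collapse = ", "))
  }
  out <- list()
  for (d in grid) {
    v <- profile[, match(d, depths)]
    sel <- which(v < threshold)
    df <- data.frame(chrom = regions$chrom[sel],
                     start = regions$start[sel],
                     end = regions$end[sel],
                     region_id = regions$region_id[sel],
                     gene = regions$gene[sel],
                     depth = rep(as.integer(d), length(sel)),
                     mpc = unname(v[sel]),
                     stringsAsFactors = FALSE)
    df$reason <- sprintf("MPC %.2f < %g at %dX", df$mpc, threshold, d)
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    out[[paste0(d, "X")]] <- df
  }
  out
}

#' Write per-depth blacklist BED files
#'
#' One BED file per depth, named `blacklist.<run_type>.<depth>X.bed`,
#' with BED name = region id and score = `round(10 * MPC)` (0-1000).
#' Optionally a combined browser track of all blacklisted intervals.
#'
#' @param blacklists Output of [blacklist_regions()].
#' @param dir Output directory (created if needed).
#' @param run_type Label used in the file names.
#' @param track Also write `blacklist.<run_type>.track.bed` with a track
#'   declaration line.
#' @return Invisibly, the paths written.
#' @export
write_blacklist <- function(blacklists, dir, run_type = "DNA",
                            track = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(blacklists)) {
    df <- blacklists[[nm]]
    rec <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                      name = df$region_id, score = round(10 * df$mpc),
                      stringsAsFactors = FALSE)
    p <- file.path(dir, sprintf("blacklist.%s.%s.bed", run_type, nm))
    write_bed(rec, p, auto_sort = TRUE)
    paths <- c(paths, p)
  }
  if (track) {
    all <- do.call(rbind, blacklists)
    rec <- data.frame(chrom = all$chrom, start = all$start, end = all$end,
                      stringsAsFactors = FALSE)
    rec$name <- if (nrow(all) > 0) {
      paste0(all$region_id, ":", all$depth, "X")
    } else character(0)
    rec$score <- round(10 * all$mpc)
    p <- file.path(dir, sprintf("blacklist.%s.track.bed", run_type))
    write_track(rec, p, track_name = paste0("blacklist_", run_type),
                description = "regions with unreliable coverage",
                auto_sort = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
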
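#' Write / read a shoebox dataset bundle
#'
#' The dataset container is a single serialized bundle (RDS, version 3,
#' uncompressed-content deterministic): shots with estimated metadata and
#' shoeboxes, plus the nominal crystal, detector and spectrum the inference
#' model uses. The ground-truth sidecar is written separately and is never
#' read by any inference stage. Identical content yields byte-identical
#' files, so reruns with the same config and seed reproduce outputs
#' bit-exactly.
#'
#' @param dataset a `spread_dataset` (from [simulate_dataset()]`$data`).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spread_dataset"))
  saveRDS(dataset, path, version = 3)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "spread_dataset")) stop("not a spread_dataset bundle")
  x
}

#' @rdname write_dataset
#' @param truth a `spread_truth` sidecar (from [simulate_dataset()]`$truth`).
#' @export
write_truth_sidecar <- function(truth, path) {
  stopifnot(inherits(truth, "spread_truth"))
  saveRDS(truth, path, version = 3)
  invisible(path)
}

#' Reflection table of a dataset
#'
#' One row per shoebox: shot id, Miller index, predicted impact position,
#' integrated counts and a perimeter background estimate (mean count over
#' the outermost pixel ring times the box area).
#'
#' @param dataset a `spread_dataset`.
#' @return data.frame with columns
#'   `shot_id, h, k, l, fast, slow, sum_counts, background_est`.
#' @export
reflection_table <- function(dataset) {
  rows <- list()
  for (shot in dataset$shots) {
    for (sb in shot$shoeboxes) {
      rows[[length(rows) + 1L]] <- data.frame(
        shot_id = shot$shot_id, h = sb$hkl[1], k = sb$hkl[2], l = sb$hkl[3],
        fast = sb$metadata$fast, slow = sb$metadata$slow,
        sum_counts = sum(sb$counts),
        background_est = perimeter_mean(sb$counts) * length(sb$counts))
    }
  }
  do.call(rbind, rows)
}

# mean count over the outer one-pixel ring of a shoebox
perimeter_mean <- function(counts) {
  nf <- nrow(counts); ns <- ncol(counts)
  if (nf <= 2 || ns <= 2) return(mean(counts))
  ring <- c(counts[1, ], counts[nf, ], counts[-c(1, nf), 1],
            counts[-c(1, nf), ns])
  mean(ring)
}

#' @rdname reflection_table
#' @param path CSV output path.
#' @export
write_reflection_table <- function(dataset, path) {
  utils::write.csv(reflection_table(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Merge background-subtracted intensities over shots
#'
#' Crude scaling-free merge for export: per shoebox, integrated counts minus
#' the perimeter background estimate, divided by the per-shot scale
#' estimate; averaged over observations of the same Miller index, with the
#' standard error of the mean as sigma (Poisson sigma for singly observed
#' reflections).
#'
#' @param dataset a `spread_dataset`.
#' @return data.frame `h, k, l, intensity, sigma, n_obs`.
#' @export
merge_intensities <- function(dataset) {
  tab <- reflection_table(dataset)
  g <- vapply(dataset$shots, function(s) s$scale_estimate, 0)
  tab$net <- (tab$sum_counts - tab$background_est) / g[tab$shot_id]
  key <- paste(tab$h, tab$k, tab$l)
  out <- do.call(rbind, lapply(split(tab, key), function(d) {
    n <- nrow(d)
    sig <- if (n > 1) stats::sd(d$net) / sqrt(n)
           else sqrt(max(d$sum_counts[1], 1)) / g[d$shot_id[1]]
    data.frame(h = d$h[1], k = d$k[1], l = d$l[1],
               intensity = mean(d$net), sigma = sig, n_obs = n)
  }))
  rownames(out) <- NULL
  out[order(out$h, out$k, out$l), ]
}

#' Export merged intensities in SHELX-style fixed-width hkl format
#'
#' Four-column fixed-width records `h k l intensity sigma` (3 x 4-wide
#' integers, 2 x 8-wide reals), as consumed by SHELX-family tools.
#'
#' @param merged data.frame from [merge_intensities()].
#' @param path output path.
#' @export
write_shelx_hkl <- function(merged, path) {
  sc <- 1
  mx <- max(abs(c(merged$intensity, merged$sigma)))
  if (mx > 0) sc <- min(1, 9999999 / mx / 100)
  lines <- sprintf("%4d%4d%4d%8.2f%8.2f", merged$h, merged$k, merged$l,
                   merged$intensity * sc, merged$sigma * sc)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0, 0, 0, 0, 0)), path)
  invisible(path)
}
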
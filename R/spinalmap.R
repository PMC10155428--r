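#' Load and validate a myotomal chart
#'
#' A myotomal chart links each recorded muscle to the lumbosacral spinal
#' segments (L1-S1) whose alpha motor neurons innervate it, with weights in
#' `[0, 1]`. The CSV has a `muscle` column plus one column per segment.
#' The built-in default (`inst/extdata/myotomal_chart_synthetic.csv`) is an
#' implementation default assembled from published Sharrard-derived
#' innervation tables for the 10 recorded muscles — replace it with your
#' own chart for substantive use.
#'
#' @param path CSV path, or `NULL` for the built-in default.
#' @param layout the [channel_layout()] the chart must cover.
#' @param segments required segment labels, in rostro-caudal order.
#' @return object of class `myotomal_chart`: `weights` (muscles x
#'   segments), `segments`, `n_j` (muscles loading each segment).
#' @export
load_myotomal_chart <- function(path = NULL, layout = channel_layout(),
                                segments = c("L1", "L2", "L3",
                                             "L4", "L5", "S1")) {
  if (is.null(path))
    path <- system.file("extdata", "myotomal_chart_synthetic.csv",
                        package = "synergykit", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"muscle" %in% names(df)) stop("chart error: no 'muscle' column")
  extra_seg <- setdiff(setdiff(names(df), "muscle"), segments)
  if (length(extra_seg))
    stop("chart error: segments outside ", paste(segments, collapse = "-"),
         ": ", paste(extra_seg, collapse = ", "))
  missing_seg <- setdiff(segments, names(df))
  if (length(missing_seg))
    stop("chart error: missing segment column ",
         paste(missing_seg, collapse = ", "))
  unknown <- setdiff(df$muscle, layout$names)
  if (length(unknown))
    stop("chart error: unknown muscle ", paste(unknown, collapse = ", "))
  missing_m <- setdiff(layout$names, df$muscle)
  if (length(missing_m))
    stop("chart error: missing muscle ", paste(missing_m, collapse = ", "))
  W <- as.matrix(df[, segments])
  rownames(W) <- df$muscle
  W <- W[layout$names, , drop = FALSE]
  if (any(!is.finite(W)) || any(W < 0) || any(W > 1))
    stop("chart error: weights must lie in [0, 1]")
  if (any(rowSums(W > 0) == 0))
    stop("chart error: muscle with no positive weight: ",
         paste(layout$names[rowSums(W > 0) == 0], collapse = ", "))
  n_j <- colSums(W > 0)
  if (any(n_j == 0))
    stop("chart error: empty segment ",
         paste(segments[n_j == 0], collapse = ", "))
  structure(list(weights = W, segments = segments, n_j = n_j),
            class = "myotomal_chart")
}

#' Write a myotomal chart to CSV
#'
#' @param chart a [load_myotomal_chart()] object.
#' @param path output CSV path.
#' @export
write_myotomal_chart <- function(chart, path) {
  df <- data.frame(muscle = rownames(chart$weights),
                   chart$weights, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.myotomal_chart <- function(x, ...) {
  cat("myotomal chart:", nrow(x$weights), "muscles x",
      length(x$segments), "segments (", paste(x$segments, collapse = " "),
      ")\n")
  print(x$weights)
  invisible(x)
}

#' Map muscle envelopes to spinal segments
#'
#' Estimated alpha-motor-neuron drive of segment `j` at sample `s` is the
#' chart-weighted average of the muscle envelopes:
#' `S[j, s] = sum_i k[i, j] E[i, s] / n_j`, with `n_j` the number of
#' muscles loading segment `j`. The map is linear in the envelope and
#' preserves non-negativity.
#'
#' @param envelope muscles x time matrix (rownames = muscles).
#' @param chart a [load_myotomal_chart()] object covering those muscles.
#' @return segments x time matrix of class `spinal_map`, carrying the
#'   envelope's `movement`/`condition` attributes.
#' @export
map_to_segments <- function(envelope, chart) {
  if (!all(rownames(envelope) %in% rownames(chart$weights)) ||
      nrow(envelope) != nrow(chart$weights))
    stop("envelope muscles do not match the chart rows")
  K <- chart$weights[rownames(envelope), , drop = FALSE]
  S <- t(K) %*% envelope / chart$n_j
  structure(S, class = c("spinal_map", class(S)),
            movement = attr(envelope, "movement"),
            condition = attr(envelope, "condition"))
}

#' Heatmap of a spinal motor-output map
#'
#' @param x a `spinal_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.spinal_map <- function(x, ...) {
  m <- unclass(x)
  graphics::image(x = seq(0, 100, length.out = ncol(m)),
                  y = seq_len(nrow(m)), z = t(m[rev(seq_len(nrow(m))), ]),
                  xlab = "task completion (%)", ylab = "",
                  yaxt = "n", col = grDevices::hcl.colors(64, "YlOrRd",
                                                          rev = TRUE),
                  main = paste("spinal map", attr(x, "movement"),
                               attr(x, "condition")), ...)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 1)
  invisible(x)
}
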
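#' Render a penscript image
#'
#' Draws one trial's ink as connected polylines, as written (the device
#' y-axis grows downward, so the axis is flipped for display). The default
#' filename follows the `<participant>_<item>_<character>.png` convention:
#' participant ID, then item number, then the character itself.
#'
#' @param tree A [segment_trial()] result (its `samples` carry the ink and
#'   the pen-in-air trace).
#' @param participant_id,item_number,target_char Trial identity used for the
#'   default filename.
#' @param out_dir Output directory.
#' @param file Optional explicit filename (overrides the convention).
#' @param format `"png"` or `"svg"`.
#' @param size Image side in pixels (png) or inches (svg).
#' @param ink_col,ink_lwd Ink colour and width.
#' @param hover Draw the pen-in-air trace as grey dots.
#' @param ascii_names Replace the character by the item number in the
#'   filename, for filesystems that reject non-ASCII names.
#' @return The path of the written file, invisibly. A trial with no strokes
#'   produces a blank image and a warning.
#' @export
render_penscript <- function(tree, participant_id, item_number, target_char,
                             out_dir = ".", file = NULL,
                             format = c("png", "svg"), size = 480,
                             ink_col = "black", ink_lwd = 2, hover = FALSE,
                             ascii_names = FALSE) {
  format <- match.arg(format)
  if (is.null(file)) {
    name_char <- if (ascii_names) item_number else target_char
    file <- sprintf("%s_%s_%s.%s", participant_id, item_number, name_char,
                    format)
  }
  path <- file.path(out_dir, file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "png") grDevices::png(path, width = size, height = size)
  else grDevices::svg(path, width = size / 96, height = size / 96)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  s <- tree$samples
  if (nrow(tree$strokes) == 0L) {
    warning("trial ", tree$trial_id, " has no strokes; blank image",
            call. = FALSE)
    graphics::plot.new()
    return(invisible(path))
  }
  ink <- s$pressure > 0
  rng_x <- range(s$x[ink]); rng_y <- range(s$y[ink])
  pad <- 0.05 * max(diff(rng_x), diff(rng_y), 1)
  graphics::plot(NA, xlim = rng_x + c(-pad, pad),
                 ylim = rev(rng_y + c(-pad, pad)),  # y grows downward
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  if (hover)
    graphics::points(s$x[!ink], s$y[!ink], col = "grey70", pch = 16,
                     cex = 0.4)
  st <- tree$strokes
  for (k in seq_len(nrow(st))) {
    i <- st$first_idx[k]:st$last_idx[k]
    graphics::lines(s$x[i], s$y[i], col = ink_col, lwd = ink_lwd)
  }
  invisible(path)
}

#' Render per-stroke diagnostic panels
#'
#' One panel per stroke, in production order. Panel k shows the ink written
#' so far (grey), the pen-in-air trace (grey dots), the current stroke
#' (purple), a green line for the jump from the previous stroke's end to the
#' current stroke's start, and annotates the stroke's metrics: `Abs RT`
#' (stroke onset minus audio offset), `Avg Pressure`, `S length`,
#' `Prev Dist`, `Start, RT` (the stroke writing latency) and `End, Dur` (the
#' stroke writing duration). Annotated values equal the metric table's to
#' printed precision.
#'
#' @param tree A [segment_trial()] result.
#' @param stroke_metrics_table The trial's rows from [stroke_metrics()].
#' @param audio_offset_ms Prompt offset, anchors `Abs RT`.
#' @param path Output file.
#' @param format `"png"` or `"svg"`.
#' @param hover Draw the pen-in-air trace.
#' @param annotate Print the metric annotations above each panel.
#' @param panel_px Pixel size of each panel (png).
#' @return `path`, invisibly.
#' @export
render_stroke_panels <- function(tree, stroke_metrics_table, audio_offset_ms,
                                 path, format = c("png", "svg"),
                                 hover = TRUE, annotate = TRUE,
                                 panel_px = 220) {
  format <- match.arg(format)
  st <- tree$strokes
  n <- nrow(st)
  if (n == 0L) stop("trial has no strokes")
  if (nrow(stroke_metrics_table) != n)
    stop("stroke metric table does not match the trial: ",
         nrow(stroke_metrics_table), " rows for ", n, " strokes")
  ncol_p <- ceiling(sqrt(n)); nrow_p <- ceiling(n / ncol_p)
  if (format == "png")
    grDevices::png(path, width = ncol_p * panel_px,
                   height = nrow_p * panel_px)
  else grDevices::svg(path, width = ncol_p * panel_px / 96,
                      height = nrow_p * panel_px / 96)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(nrow_p, ncol_p), mar = c(0.5, 0.5, 2.2, 0.5))
  s <- tree$samples
  ink <- s$pressure > 0
  rng_x <- range(s$x[ink]); rng_y <- range(s$y[ink])
  pad <- 0.05 * max(diff(rng_x), diff(rng_y), 1)
  for (k in seq_len(n)) {
    graphics::plot(NA, xlim = rng_x + c(-pad, pad),
                   ylim = rev(rng_y + c(-pad, pad)), asp = 1, axes = FALSE,
                   xlab = "", ylab = "")
    if (hover)
      graphics::points(s$x[!ink & s$t < st$onset_t[k]],
                       s$y[!ink & s$t < st$onset_t[k]],
                       col = "grey70", pch = 16, cex = 0.35)
    for (j in seq_len(k - 1L)) {
      i <- st$first_idx[j]:st$last_idx[j]
      graphics::lines(s$x[i], s$y[i], col = "grey45", lwd = 1.5)
    }
    if (k > 1L)
      graphics::segments(st$end_x[k - 1L], st$end_y[k - 1L],
                         st$start_x[k], st$start_y[k],
                         col = "forestgreen", lwd = 1.2, lty = 2)
    i <- st$first_idx[k]:st$last_idx[k]
    graphics::lines(s$x[i], s$y[i], col = "purple", lwd = 2.5)
    if (!annotate) next
    m <- stroke_metrics_table[k, ]
    abs_rt <- st$onset_t[k] - audio_offset_ms
    lab1 <- sprintf("S%d  Abs RT %.0f ms  Avg Pressure %.0f", k, abs_rt,
                    m$pressure)
    lab2 <- sprintf("S length %.2f  Prev Dist %s", m$length,
                    if (is.na(m$distance)) "-" else sprintf("%.2f", m$distance))
    lab3 <- sprintf("Start, RT %s  End, Dur %.0f ms",
                    if (is.na(m$latency_ms)) "-"
                    else sprintf("%.0f ms", m$latency_ms),
                    m$duration_ms)
    graphics::mtext(paste(lab1, lab2, lab3, sep = "\n"), side = 3, line = 0,
                    cex = 0.45)
  }
  invisible(path)
}
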
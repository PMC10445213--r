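# Delimited-text I/O for the pipeline file formats. All files are plain CSV
# with an optional metadata header of '#'-prefixed lines (version, seed,
# parameters); readers skip such lines.

required_cols <- list(
  samples = c("subject", "session", "part", "instruction", "trial", "t_ms",
              "x_px", "y_px", "valid"),
  clicks = c("subject", "session", "part", "instruction", "trial", "t_ms",
             "x_px", "y_px"),
  layout = c("part", "trial", "label", "seq_index", "x_deg", "y_deg",
             "radius"),
  scores = c("subject_id", "session", "part", "instruction", "trial"),
  events = c("subject", "session", "part", "instruction", "trial", "kind",
             "onset_ms", "offset_ms", "x_deg", "y_deg", "amplitude_deg"))

write_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tmtgaze %s",
                     as.character(utils::packageVersion("tmtgaze"))), con)
  if (!is.null(meta))
    for (nm in names(meta))
      writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_checked <- function(path, kind) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required_cols[[kind]], names(df))
  if (length(missing))
    stop("schema error in ", basename(path), ": missing required column ",
         paste(missing, collapse = ", "))
  df
}

check_monotone <- function(df, timecol) {
  key <- interaction(df$subject, df$session, df$part, df$instruction,
                     df$trial, drop = TRUE)
  for (lev in levels(key)) {
    tt <- df[[timecol]][key == lev]
    if (any(diff(tt) < 0))
      stop("data error: non-monotone timestamps within trial ", lev)
  }
  invisible(df)
}

#' Read a raw gaze samples file
#'
#' Expects CSV columns `subject`, `session`, `part`, `instruction`, `trial`,
#' `t_ms`, `x_px`, `y_px`, `valid`; `#` lines are metadata. Timestamps must be
#' non-decreasing within each trial.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_samples <- function(path) {
  df <- read_table_checked(path, "samples")
  check_monotone(df, "t_ms")
}

#' Read a mouse-clicks file
#' @inheritParams read_samples
#' @export
read_clicks <- function(path) {
  df <- read_table_checked(path, "clicks")
  check_monotone(df, "t_ms")
}

#' Read a target-layout file
#' @inheritParams read_samples
#' @export
read_layout <- function(path) read_table_checked(path, "layout")

#' Read a per-trial scores file
#' @inheritParams read_samples
#' @export
read_scores <- function(path) read_table_checked(path, "scores")

#' Write a gaze samples file
#' @param df data frame in the samples schema.
#' @param path file path.
#' @param meta optional named list written as `# key: value` header lines.
#' @export
write_samples <- function(df, path, meta = NULL) write_with_meta(df, path, meta)

#' Write a clicks file
#' @inheritParams write_samples
#' @export
write_clicks <- function(df, path, meta = NULL) write_with_meta(df, path, meta)

#' Write a layout file
#' @inheritParams write_samples
#' @export
write_layout <- function(df, path, meta = NULL) write_with_meta(df, path, meta)

#' Write a per-trial scores file
#' @inheritParams write_samples
#' @export
write_scores <- function(df, path, meta = NULL) write_with_meta(df, path, meta)

#' Flatten a dataset's layouts to the layout file schema
#' @param dataset a [generate_dataset()] result.
#' @return a data frame in the layout schema.
#' @export
layouts_to_table <- function(dataset) {
  rows <- lapply(names(dataset$layouts), function(nm) {
    lay <- dataset$layouts[[nm]]
    data.frame(part = attr(lay, "part"),
               trial = as.integer(sub("^[AB]", "", nm)),
               label = lay$label, seq_index = lay$seq_index,
               x_deg = lay$x, y_deg = lay$y, radius = lay$radius,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flatten a dataset's clicks to the clicks file schema (pixel coordinates)
#' @param dataset a [generate_dataset()] result.
#' @param geometry a [screen_geometry()] used for the degree-to-pixel
#'   conversion.
#' @return a data frame in the clicks schema.
#' @export
clicks_to_table <- function(dataset, geometry = screen_geometry()) {
  idx <- dataset$trials$index
  rows <- lapply(seq_len(nrow(idx)), function(i) {
    tr <- dataset$trials$trial[[i]]
    p <- deg_to_px(tr$clicks$x, tr$clicks$y, geometry)
    data.frame(subject = idx$subject_id[i], session = idx$session[i],
               part = idx$part[i], instruction = idx$instruction[i],
               trial = idx$trial[i], t_ms = tr$clicks$t,
               x_px = p$x, y_px = p$y, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
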
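# Landmark file I/O.
#
# Two plain-text formats are supported:
#  * delimited: one row per landmark with columns
#    subject_id, modality, landmark_index (1-6), x, y;
#  * TPS morphometrics blocks: "LM=6", six coordinate lines, then
#    "IMAGE=<modality>" and "ID=<subject>". Coordinates are written as
#    given; no unit conversion is performed.

#' Flatten a cohort (or list) into a list of landmark sets
#' @noRd
collect_landmark_sets <- function(x) {
  if (inherits(x, "landmark_set")) return(list(x))
  if (inherits(x, "rugae_cohort")) {
    mods <- names(x$models)
    return(unlist(lapply(x$subjects, function(s) s[mods]),
                  recursive = FALSE))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "landmark_set")))
    return(x)
  rug_abort("x must be a landmark_set, a list of them, or a rugae_cohort",
            "rugometry_invalid_input")
}

#' Write landmark sets to a delimited or TPS text file
#'
#' @param x A [landmark_set()], a list of them, or a `rugae_cohort`.
#' @param file Output path.
#' @param format `"delim"` (tab-separated long table) or `"tps"`.
#' @return Invisibly, `file`.
#' @export
write_landmarks <- function(x, file, format = c("delim", "tps")) {
  format <- match.arg(format)
  sets <- collect_landmark_sets(x)
  if (format == "delim") {
    df <- do.call(rbind, lapply(sets, function(s) {
      data.frame(subject_id = s$subject_id, modality = s$modality,
                 landmark_index = 1:6, x = s$pts[, 1L], y = s$pts[, 2L],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    lines <- unlist(lapply(sets, function(s) {
      c("LM=6",
        sprintf("%.10g %.10g", s$pts[, 1L], s$pts[, 2L]),
        sprintf("IMAGE=%s", s$modality),
        sprintf("ID=%s", s$subject_id))
    }))
    writeLines(lines, file)
  }
  invisible(file)
}

#' Read landmark sets from a delimited or TPS text file
#'
#' @param file Input path.
#' @param format `"auto"` (by extension: `.tps` means TPS, anything else
#'   delimited), `"delim"`, or `"tps"`.
#' @return Named list of [landmark_set()] objects
#'   (names `"<subject>.<modality>"`).
#' @export
read_landmarks <- function(file, format = c("auto", "delim", "tps")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tps$", file, ignore.case = TRUE)) "tps" else "delim"
  if (format == "delim") {
    df <- utils::read.table(file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("subject_id", "modality", "landmark_index", "x", "y")
    if (!all(need %in% names(df)))
      rug_abort(sprintf("landmark file must have columns: %s",
                        paste(need, collapse = ", ")),
                "rugometry_invalid_input")
    key <- interaction(df$subject_id, df$modality, drop = TRUE)
    sets <- lapply(split(df, key), function(g) {
      g <- g[order(g$landmark_index), ]
      if (!identical(as.integer(g$landmark_index), 1:6))
        rug_abort(sprintf("subject %s/%s: landmark indices must be exactly 1..6",
                          g$subject_id[1L], g$modality[1L]),
                  "rugometry_invalid_input")
      landmark_set(cbind(g$x, g$y), g$modality[1L], g$subject_id[1L])
    })
    return(sets)
  }
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines)
  if (length(starts) == 0L)
    rug_abort("no LM= blocks found in TPS file", "rugometry_invalid_input")
  ends <- c(starts[-1L] - 1L, length(lines))
  sets <- list()
  for (bi in seq_along(starts)) {
    block <- lines[starts[bi]:ends[bi]]
    n_lm <- as.integer(sub("^LM=", "", block[1L]))
    if (is.na(n_lm) || n_lm != 6L)
      rug_abort("each TPS block must declare LM=6", "rugometry_invalid_input")
    coords <- do.call(rbind, lapply(block[2:(1L + n_lm)], function(l) {
      as.numeric(strsplit(l, "[[:space:]]+")[[1L]])
    }))
    idline <- grep("^ID=", block, value = TRUE)
    imline <- grep("^IMAGE=", block, value = TRUE)
    sid <- if (length(idline)) sub("^ID=", "", idline[1L]) else
      sprintf("block%d", bi)
    mod <- if (length(imline)) sub("^IMAGE=", "", imline[1L]) else "unknown"
    lm <- landmark_set(coords, mod, sid)
    sets[[paste(sid, mod, sep = ".")]] <- lm
  }
  sets
}
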
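#' Timbre-descriptor feature vector (24 entries)
#'
#' Ten frame-wise spectral descriptors (see [spectral_descriptors()]) are each
#' summarized by their median and interquartile range over frames (frames with
#' undefined descriptors excluded), giving 20 values; the four temporal
#' descriptors of [temporal_descriptors()] complete the 24-entry vector.
#'
#' @param clip An `audio_clip`.
#' @param n_bands Gammatone bands for the spectral decomposition (default 64).
#' @return Named numeric vector of length 24 (`tt.centroid.med`,
#'   `tt.centroid.iqr`, ..., `tt.modfreq`, `tt.modamp`, `tt.zcr.med`,
#'   `tt.zcr.iqr`).
#' @export
extract_tt <- function(clip, n_bands = 64L) {
  tf <- gammatone_decompose(clip, n_bands = n_bands)
  sp <- spectral_descriptors(tf)
  med <- vapply(sp, stats::median, 0, na.rm = TRUE)
  iqr <- vapply(sp, stats::IQR, 0, na.rm = TRUE)
  # silent clip: every frame undefined -> summaries 0 by convention
  med[is.na(med)] <- 0
  iqr[is.na(iqr)] <- 0
  spectral <- as.numeric(rbind(med, iqr))
  names(spectral) <- as.vector(rbind(paste0("tt.", names(sp), ".med"),
                                     paste0("tt.", names(sp), ".iqr")))
  tmp <- temporal_descriptors(clip)
  names(tmp) <- c("tt.modfreq", "tt.modamp", "tt.zcr.med", "tt.zcr.iqr")
  c(spectral, tmp)
}

#' Build a clips x features table
#'
#' Extracts the requested feature sets for every clip and assembles them into
#' a feature table: one row per clip, one column per named feature. The
#' combined `tt` + `mfcc` table has 48 feature columns.
#'
#' @param clips Named list of `audio_clip` objects (at least 2).
#' @param sets Character subset of `c("tt", "mfcc")`.
#' @return data.frame with first column `clip_id` followed by numeric feature
#'   columns; column order is fixed (tt block, then mfcc block).
#' @export
build_feature_table <- function(clips, sets = c("tt", "mfcc")) {
  sets <- match.arg(sets, c("tt", "mfcc"), several.ok = TRUE)
  if (length(clips) < 2L) stop("at least 2 clips are required")
  rows <- lapply(clips, function(cl) {
    id <- if (inherits(cl, "audio_clip")) cl$clip_id else "<unnamed>"
    tryCatch({
      v <- numeric()
      if ("tt" %in% sets) v <- c(v, extract_tt(cl))
      if ("mfcc" %in% sets) v <- c(v, extract_mfcc(cl))
      if (any(!is.finite(v)))
        stop("non-finite feature value: ",
             paste(names(v)[!is.finite(v)], collapse = ", "))
      v
    }, error = function(e) {
      stop("feature extraction failed for clip '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
  })
  ids <- vapply(clips, function(cl)
    if (inherits(cl, "audio_clip")) cl$clip_id else NA_character_, "")
  tab <- as.data.frame(do.call(rbind, rows))
  data.frame(clip_id = unname(ids), tab, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# Numeric matrix view of a feature table (rownames = clip ids).
feature_matrix <- function(table) {
  stopifnot(is.data.frame(table), "clip_id" %in% names(table))
  m <- as.matrix(table[, setdiff(names(table), "clip_id"), drop = FALSE])
  rownames(m) <- table$clip_id
  m
}
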
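# CSV readers/writers and validators for the two tables the pipeline consumes:
# per-sample congener concentrations and participant spirometry/anthropometrics.
#
# samples.csv:      sample_id, season, sampler_kind, participant_id,
#                   duration_h, pm25, <one column per congener, ng/m3>
# participants.csv: participant_id, sex, age_y, height_cm, weight_kg,
#                   tidal_volume_L, breathing_rate_per_min, season
#
# Nondetects are written as the token "ND" and, on reading, stored as 0 with a
# logical nondetect flag (attribute "nondetect"); an LOD/2 substitution is
# selectable. Missing values stay NA -- never silent zeros.

SEASONS <- c("heating", "non-heating")
SAMPLER_KINDS <- c("personal", "fixed_indoor", "fixed_outdoor")
SAMPLE_META_COLS <- c("sample_id", "season", "sampler_kind",
                      "participant_id", "duration_h", "pm25")
PARTICIPANT_COLS <- c("participant_id", "sex", "age_y", "height_cm",
                      "weight_kg", "tidal_volume_L",
                      "breathing_rate_per_min", "season")
SEXES <- c("boy", "girl")
ND_TOKENS <- c("ND", "nd", "<LOD")

#' Read a sample-level PAH concentration table
#'
#' Reads and validates `samples.csv`: one row per PM2.5 filter sample with
#' metadata and per-congener concentrations (ng/m3) aligned to the registry.
#'
#' @param path Path to the CSV file.
#' @param registry A `pah_registry`; the congener columns must match its
#'   abbreviations exactly (same set, same order).
#' @param nondetect Policy for below-detection values (`"ND"` cells):
#'   `"zero"` (default) stores 0, `"half_lod"` stores `lod/2`.
#' @param lod Named numeric vector of detection limits (ng/m3) per congener;
#'   required for the `"half_lod"` policy.
#'
#' @return Data frame of class `pah_samples` with the schema columns; the
#'   logical matrix of nondetect flags is attached as attribute `"nondetect"`.
#'
#' @examples
#' reg <- load_registry()
#' coh <- generate_cohort(generator_spec(seed = 1))
#' tmp <- tempfile(fileext = ".csv")
#' write_pah_samples(coh$samples, tmp)
#' nrow(read_pah_samples(tmp, reg)) == nrow(coh$samples)
#' @export
read_pah_samples <- function(path, registry = load_registry(),
                             nondetect = c("zero", "half_lod"), lod = NULL) {
  nondetect <- match.arg(nondetect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  expected <- c(SAMPLE_META_COLS, registry$abbreviation)
  if (!identical(names(raw), expected)) {
    stop("malformed header in ", path, ": expected columns ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  congeners <- registry$abbreviation

  out <- data.frame(
    sample_id = raw$sample_id,
    season = raw$season,
    sampler_kind = raw$sampler_kind,
    participant_id = ifelse(raw$participant_id %in% c("", "NA"),
                            NA_character_, raw$participant_id),
    duration_h = as.numeric(raw$duration_h),
    pm25 = as.numeric(raw$pm25),
    stringsAsFactors = FALSE
  )

  nd <- matrix(FALSE, nrow(raw), length(congeners),
               dimnames = list(NULL, congeners))
  for (cg in congeners) {
    cell <- raw[[cg]]
    is_nd <- cell %in% ND_TOKENS
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_nd & is.na(val) & !(cell %in% c("", "NA"))
    if (any(bad)) {
      stop("non-numeric value for ", cg, " in row ",
           which(bad)[1], " of ", path, call. = FALSE)
    }
    if (any(is_nd)) {
      sub <- if (nondetect == "half_lod") {
        if (is.null(lod) || is.na(lod[cg])) {
          stop("half_lod policy requires an LOD for ", cg, call. = FALSE)
        }
        lod[[cg]] / 2
      } else 0
      val[is_nd] <- sub
    }
    neg <- !is.na(val) & val < 0
    if (any(neg)) {
      stop("negative concentration for ", cg, " in row ",
           which(neg)[1], " of ", path, call. = FALSE)
    }
    out[[cg]] <- val
    nd[, cg] <- is_nd
  }

  out <- validate_samples(out, congeners)
  attr(out, "nondetect") <- nd
  class(out) <- c("pah_samples", "data.frame")
  out
}

validate_samples <- function(df, congeners) {
  bad_season <- !df$season %in% SEASONS
  if (any(bad_season)) {
    stop("unknown season token in row ", which(bad_season)[1],
         " (expected one of: ", paste(SEASONS, collapse = ", "), ")",
         call. = FALSE)
  }
  bad_kind <- !df$sampler_kind %in% SAMPLER_KINDS
  if (any(bad_kind)) {
    stop("unknown sampler_kind token in row ", which(bad_kind)[1],
         call. = FALSE)
  }
  bad_dur <- is.na(df$duration_h) | df$duration_h <= 0
  if (any(bad_dur)) {
    stop("duration_h must be positive (row ", which(bad_dur)[1], ")",
         call. = FALSE)
  }
  if (any(!is.na(df$pm25) & df$pm25 < 0)) {
    stop("pm25 must be nonnegative", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1],
         call. = FALSE)
  }
  df
}

#' Write a sample table to CSV
#'
#' Inverse of [read_pah_samples()]; numeric values are formatted at 6
#' significant digits and nondetect-flagged cells are written as `"ND"`.
#'
#' @param samples A `pah_samples` data frame (or compatible plain data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pah_samples <- function(samples, path) {
  df <- as.data.frame(samples)
  nd <- attr(samples, "nondetect")
  num_cols <- setdiff(names(df), c("sample_id", "season", "sampler_kind",
                                   "participant_id"))
  for (cl in num_cols) {
    col <- fmt_num(df[[cl]])
    if (!is.null(nd) && cl %in% colnames(nd)) col[nd[, cl]] <- "ND"
    df[[cl]] <- col
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(signif(v, 6), scientific = FALSE,
                                            trim = TRUE)
  }, character(1))
  out
}

#' Keep only valid personal samples
#'
#' Personal pump samples are valid when the pump ran between 22 and 26 hours
#' (inclusive); fixed-site samples (48-hour middle-flow samplers) pass through
#' untouched.
#'
#' @param samples A `pah_samples` data frame.
#' @return The subset, same class and attributes.
#' @examples
#' coh <- generate_cohort(generator_spec(seed = 1))
#' nrow(filter_valid_personal(coh$samples))
#' @export
filter_valid_personal <- function(samples) {
  keep <- samples$sampler_kind != "personal" |
    (samples$duration_h >= 22 & samples$duration_h <= 26)
  out <- samples[keep, , drop = FALSE]
  nd <- attr(samples, "nondetect")
  if (!is.null(nd)) attr(out, "nondetect") <- nd[keep, , drop = FALSE]
  class(out) <- class(samples)
  out
}

#' Read a participant table
#'
#' Reads and validates `participants.csv`: one row per child with sex, age,
#' anthropometrics and spirometry (tidal volume, breathing frequency).
#'
#' @param path Path to the CSV file.
#' @return Data frame of class `pah_participants`.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 strip.white = TRUE)
  if (!identical(names(df), PARTICIPANT_COLS)) {
    stop("malformed header in ", path, ": expected columns ",
         paste(PARTICIPANT_COLS, collapse = ", "), call. = FALSE)
  }
  for (cl in c("age_y", "height_cm", "weight_kg", "tidal_volume_L",
               "breathing_rate_per_min")) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  validate_participants(df)
}

validate_participants <- function(df) {
  bad_sex <- !df$sex %in% SEXES
  if (any(bad_sex)) {
    stop("unknown sex token in row ", which(bad_sex)[1],
         " (expected one of: ", paste(SEXES, collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!df$season %in% SEASONS)) {
    stop("unknown season token in participants table", call. = FALSE)
  }
  for (cl in c("weight_kg", "tidal_volume_L", "breathing_rate_per_min")) {
    bad <- is.na(df[[cl]]) | df[[cl]] <= 0
    if (any(bad)) {
      stop(cl, " must be positive (row ", which(bad)[1], ")", call. = FALSE)
    }
  }
  if (anyDuplicated(df$participant_id)) {
    stop("duplicate participant_id", call. = FALSE)
  }
  class(df) <- c("pah_participants", "data.frame")
  df
}

#' Write a participant table to CSV
#'
#' @param participants A `pah_participants` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  df <- as.data.frame(participants)
  for (cl in c("age_y", "height_cm", "weight_kg", "tidal_volume_L",
               "breathing_rate_per_min")) {
    df[[cl]] <- fmt_num(df[[cl]])
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
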
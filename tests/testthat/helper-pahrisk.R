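# Shared fixtures built in code.

REG <- load_registry()
TEFS <- tef_table(REG)

# Build a one-row sample data frame with the full schema; congener
# concentrations default to 0.1 ng/m3 unless overridden.
make_sample <- function(sample_id = "S1", season = "heating",
                        sampler_kind = "personal", participant_id = NA,
                        duration_h = 24, pm25 = 230, ...,
                        fill = 0.1) {
  conc <- setNames(rep(fill, nrow(REG)), REG$abbreviation)
  dots <- list(...)
  conc[names(dots)] <- unlist(dots)
  df <- cbind(
    data.frame(sample_id = sample_id, season = season,
               sampler_kind = sampler_kind,
               participant_id = as.character(participant_id),
               duration_h = duration_h, pm25 = pm25,
               stringsAsFactors = FALSE),
    as.data.frame(as.list(conc))
  )
  class(df) <- c("pah_samples", "data.frame")
  df
}

bind_samples <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("pah_samples", "data.frame")
  df
}

# Small default cohort reused across files (38 participants, seeded).
default_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- generate_cohort(generator_spec(seed = 42))
    coh
  }
})
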
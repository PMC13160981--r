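# Small fixture builders, generated in code at test time.

make_samples <- function(pressure, t = seq_along(pressure) * 5,
                         x = seq_along(pressure), y = rep(0, length(pressure)),
                         trial_id = 1L) {
  data.frame(trial_id = rep(trial_id, length(pressure)), t = t, x = x, y = y,
             pressure = pressure)
}

make_events <- function(trial_id = 1L, participant_id = 1L, item_number = 1L,
                        target_char = "稻", audio_offset_ms = 1000,
                        self_report = 0L, space_press_ms = NULL) {
  data.frame(trial_id = trial_id, participant_id = participant_id,
             item_number = item_number, target_char = target_char,
             audio_onset_ms = audio_offset_ms - 500,
             audio_offset_ms = audio_offset_ms,
             space_press_ms = if (is.null(space_press_ms))
               audio_offset_ms + 60000 else space_press_ms,
             self_report = self_report, stringsAsFactors = FALSE)
}

# a small complete simulated experiment shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(sim_config(n_participants = 4L,
                                            n_items = 30L, seed = 2024L))
    cache
  }
})
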
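# shared builders for small in-code fixtures

toy_colonies <- function(x, y, gravid = TRUE, area = 1,
                         depth = "shallow", ids = NULL) {
  n <- length(x)
  validate_colony_table(data.frame(
    colony_id = ids %||% sprintf("T%02d", seq_len(n)),
    x = x, y = y,
    planar_area = rep_len(area, n),
    gravid = rep_len(gravid, n),
    depth_class = rep_len(depth, n),
    stringsAsFactors = FALSE))
}

toy_events <- function(ids, night, minute, extent = "partial",
                       observer = "obsA") {
  validate_spawn_events(data.frame(
    colony_id = ids, night = night,
    release_minute = as.integer(minute),
    extent = rep_len(extent, length(ids)),
    observer_id = rep_len(observer, length(ids)),
    stringsAsFactors = FALSE))
}

toy_samples <- function(ids, night, k, n = 200) {
  validate_fert_samples(data.frame(
    colony_id = ids, night = night,
    n_scored = rep_len(n, length(ids)), n_fertilized = k,
    n_damage_scored = 0L, n_damaged = 0L,
    dispersal_group = NA_character_,
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
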
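# Shared fixture builders: everything is generated in code at test time.

# a compact 2-3 year fleet for pipeline and estimation tests
mini_scenario <- function(n_years = 2, effort = c(300, 350),
                          coverage = c(0.5, 0.4), mu_alpha = -2.2) {
  scenario_config(n_years = n_years, first_year = 2004,
                  effort_per_year = effort, coverage = coverage,
                  mu_alpha = mu_alpha, sigma_alpha = 0.4)
}

# hand-built tow tibble with fully controlled fields
make_tows <- function(n = 4, vessel = "V01", length_m = 100,
                      start = as.POSIXct("2005-01-10 20:00:00", tz = "UTC"),
                      target = "JMA") {
  tibble::tibble(
    tow_id = sprintf("T%03d", seq_len(n)),
    vessel_id = vessel,
    vessel_length = length_m,
    trip_id = NA_character_,
    start_time = start + (seq_len(n) - 1) * 6 * 3600,
    end_time = start + (seq_len(n) - 1) * 6 * 3600 + 4 * 3600,
    start_lat = -38.5, start_lon = 172.0,
    end_lat = -38.45, end_lon = 172.05,
    target_species = target,
    catch_weight = 20, groundline_depth = 80, headline_height = 30,
    trawl_speed = 4.5, bottom_depth = 150,
    observed = FALSE, captures = NA_integer_
  )
}
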
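# Shared fixtures built in code.

# trip from a speed vector (km/h), default 1 Hz timeline
make_trip <- function(speeds, t = seq_along(speeds) - 1, driver = "D1",
                      id = "T1") {
  trip(driver, id, tibble::tibble(t = t, speed = speeds))
}

log_header <- paste(
  "duration", "time", "distance (miles)", "speed (mph)", "latitude (WGS84)",
  "longitude (WGS84)", "altitude (feet)", "latitude (BD09)",
  "longitude (BD09)", sep = ","
)

# one raw app-dialect log line
log_line <- function(t, speed_mph, distance = 0.1, lat = 3.7, lon = 101.5,
                     alt = 200, time = "08:00:00") {
  paste(t, time, distance, speed_mph, lat, lon, alt, lat + 0.006, lon + 0.0065,
        sep = ",")
}

make_log <- function(...) c(log_header, ...)
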
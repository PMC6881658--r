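# shared fixtures for the suite

group_named <- function(g) {
  tab <- default_exposure_groups()
  tab[tab$name == g, ]
}

# small, fully georeferenced well set on a unit-degree square
toy_wells <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    lon = c(0, 1, 0, 1),
    lat = c(0, 0, 1, 1),
    cf = c(10, 20, 30, 40),
    stringsAsFactors = FALSE
  )
}

expect_printed_equal <- function(x, printed, digits = 4) {
  expect_equal(round_printed(x, digits), printed, tolerance = 1e-12)
}
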
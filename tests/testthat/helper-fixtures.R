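# Shared fixtures: everything is built in code at test time.

base_params <- function() {
  load_params(system.file("extdata", "base_case.json", package = "strokecea"))
}

# Life table with explicit ages/qx, round-tripped through the CSV reader so
# the tests exercise the documented interface.
make_lt <- function(age, qx) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(age = age, qx = format(qx, digits = 17)),
                   f, row.names = FALSE, quote = FALSE)
  read_life_table(f)
}

# Constant annual death probability over a wide age range.
const_lt <- function(q, min_age = 50, max_age = 120) {
  make_lt(seq(min_age, max_age), rep(q, max_age - min_age + 1))
}

# Minimal stand-in for a cohort result, for CEA arithmetic tests.
fake_cohort <- function(cost, qaly, strategy = "EVT") {
  structure(list(strategy = strategy, total_cost = cost, total_qaly = qaly),
            class = "strokecea_cohort")
}

expect_rel <- function(got, target, tol) {
  expect_lt(abs(got - target) / abs(target), tol)
}
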
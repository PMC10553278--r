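# small attribute spaces and canned designs used across the test files

tiny_attrs <- function() {
  dce_attributes(
    dce_attribute("svc", c("basic", "plus", "premium")),
    dce_attribute("fee", c("0", "10", "20"),
                  coding = "continuous", level_values = c(0, 10, 20))
  )
}

two_attrs_2x2 <- function() {
  dce_attributes(
    dce_attribute("a", c("lo", "hi")),
    dce_attribute("b", c("lo", "hi"))
  )
}

# a fixed small design over the tiny space: 4 sets, 1 block
tiny_design <- function(seed = 11) {
  attrs <- tiny_attrs()
  full <- enumerate_full_factorial(attrs)
  sets <- pair_profiles(full[c(1, 9, 2, 6, 3, 8, 4, 7), ], seed = seed)
  block_design(sets, n_blocks = 1, seed = seed, attrs = attrs)
}

# simulated tiny-space cohort (single group unless sizes given)
tiny_choices <- function(beta = c(svc.plus = 0.4, svc.premium = 0.9,
                                  fee = -0.05),
                         n = c(intervention = 40L, control = 0L),
                         seed = 5) {
  simulate_choices(tiny_attrs(), beta, design = tiny_design(),
                   n_respondents = n, sets_per_respondent = 4L, seed = seed)
}

# hand-built choice data: one respondent, one set, alternatives differing
# only on the fee column by `delta`, alternative A chosen
one_set_choices <- function(delta = log(3)) {
  data.frame(
    respondent_id = "r1", group = "intervention", set_id = 1L, block = 1L,
    alternative = c("A", "B"), svc = c(1L, 1L), fee = c(2L, 1L),
    chosen = c(1L, 0L)
  )
}
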
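# Shared fixtures, all built in code.

# one person, one task, three alternatives A/B/C with B chosen
toy_task_df <- function() {
  data.frame(
    person_id = 1, task_id = 1, alt_id = c("A", "B", "C"),
    chosen = c(FALSE, TRUE, FALSE),
    x = c(0.5, 1.0, -0.2), price = c(1, 2, 3)
  )
}

toy_choice_data <- function() {
  choice_data(toy_task_df(), choice = "chosen")
}

# small binary-logit-style DCE with one normal taste and a fixed price
# coefficient; used across fitting tests
two_alt_config <- function(mu = 1, sigma = 0.8, price = -0.5) {
  taste_config(
    x = list(family = "normal", params = list(mu = mu, sigma = sigma)),
    price = list(family = "fixed", params = list(value = price))
  )
}

two_alt_design <- function() {
  list(n_alts = 2,
       attributes = list(x = c(0, 1), price = c(0, 1, 2, 3)))
}

two_alt_spec <- function(dist = "normal") {
  model_spec(list(coef_spec("x", dist),
                  coef_spec("price", "fixed")))
}

# single-coefficient config/design/spec for oracle comparisons
one_coef_design <- function() {
  list(n_alts = 2, attributes = list(x = c(0, 1)))
}
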
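test_that("parameter table flags structural and sampled constants", {
  tab <- param_table(default_parameters())
  expect_true(all(c("parameter", "value", "sampled", "scanned") %in% names(tab)))
  scales <- grepl("expression_scale$", tab$parameter)
  expect_false(any(tab$sampled[scales]) || any(tab$scanned[scales]))
  hills <- grepl("_n$", tab$parameter)
  expect_false(any(tab$sampled[hills]))
  expect_true(all(tab$scanned[hills]))
  # the proteotoxic stressor program is an imposed protocol, not cell machinery
  expect_false(tab$sampled[tab$parameter == "tau.production_basal"])
  expect_true(tab$sampled[tab$parameter == "ros.age_production"])
})

test_that("get_param/set_param round-trip without mutating the input", {
  p <- default_parameters()
  p2 <- set_param(p, "nodes.skn1.input_K", 0.42)
  expect_equal(get_param(p2, "nodes.skn1.input_K"), 0.42)
  expect_equal(get_param(p, "nodes.skn1.input_K"),
               default_parameters()$nodes$skn1$input_K)
  p3 <- set_param(p, "ros.clearance_weights.sod2", 0.5)
  expect_equal(get_param(p3, "ros.clearance_weights.sod2"), 0.5)
  expect_error(get_param(p, "nodes.skn1.bogus"), "unknown parameter")
  expect_error(set_param(p, "nodes.bogus.input_K", 1), "unknown parameter")
})

test_that("validation enforces the structural invariants", {
  p <- default_parameters()
  expect_silent(validate_parameters(p))
  expect_error(validate_parameters(set_param(p, "nodes.skn1.input_n", 0.5)),
               ">= 1")
  expect_error(validate_parameters(set_param(p, "nodes.skn1.input_K", -1)))
  expect_error(
    validate_parameters(set_param(p, "nodes.uprmt_hsp60.self_feedback_n", 1.5)),
    "bistability")
  expect_error(validate_parameters(set_param(p, "tau.production_basal", -0.1)),
               "non-negative")
})

test_that("scenarios apply the tau doubling and skn-1 expression scalings", {
  base <- default_parameters()
  normal <- apply_scenario(base, scenario_config("normal"))
  expect_equal(param_table(normal)$value, param_table(base)$value)

  tau <- apply_scenario(base, scenario_config("tau"))
  expect_equal(tau$tau$scenario_multiplier, 2.0)

  abl <- apply_scenario(base, scenario_config("skn1-ablation"))
  expect_equal(abl$nodes$skn1$expression_scale, 0.10)
  oe <- apply_scenario(base, scenario_config("skn1-oe"))
  expect_equal(oe$nodes$skn1$expression_scale, 1.50)
  # the base object is untouched
  expect_equal(base$nodes$skn1$expression_scale, 1.0)

  expect_error(scenario_config("custom", node_scales = c(skn2 = 0.5)),
               "unknown node")
  expect_error(scenario_config("no-such-scenario"), "unknown scenario")
})

test_that("config validation catches out-of-range run settings", {
  expect_error(scenario_config(n_cells = 0), "n_cells")
  expect_error(scenario_config(dt = 0.5), "dt")
  expect_error(scenario_config(duration = -1), "duration")
  expect_error(scenario_config(heterogeneity_cv = -0.1), "heterogeneity_cv")
})

test_that("agent sampling has the stated truncated-Gaussian moments", {
  base <- default_parameters()
  expect_equal(param_table(sample_agent_params(base, 0))$value,
               param_table(base)$value)
  expect_warning(sample_agent_params(base, 0.4), "truncation")

  set.seed(101)
  pop <- agevuln:::sample_population_params(base, 2e4, 0.1)
  draws <- pop$ros$age_production
  expect_length(draws, 2e4)
  base_val <- base$ros$age_production
  expect_lt(abs(mean(draws) / base_val - 1), 0.01)
  expect_lt(abs(sd(draws) / mean(draws) / 0.1 - 1), 0.10)
  expect_true(all(draws > 0))
  expect_true(all(draws >= base_val * 0.7 - 1e-12 &
                    draws <= base_val * 1.3 + 1e-12))
  # structural leaves stay scalar
  expect_length(pop$nodes$skn1$input_n, 1)
  expect_length(pop$tau$production_basal, 1)
})

test_that("network topology exports as a signed edge list", {
  edges <- network_edges()
  expect_true(all(c("source", "target", "sign", "K", "n") %in% names(edges)))
  expect_true(all(edges$sign %in% c("+", "-")))
  expect_true(any(edges$source == "ros" & edges$target == "skn1" & edges$sign == "+"))
  expect_true(any(edges$source == "mtor" & edges$target == "bec1" & edges$sign == "-"))
  expect_true(any(edges$source == "uprmt_hsp60" & edges$target == "uprmt_hsp60"))
})
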
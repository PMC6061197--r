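# Single-neuron model: derivatives, reset rule, rest states, nullclines and
# bifurcation currents.

test_that("class parameter sets carry the published constants", {
  p <- neuron_params("RS")
  expect_equal(c(p$a, p$b, p$c, p$d), c(0.02, 0.2, -65, 8))
  expect_equal(c(p$alpha, p$beta, p$gamma, p$v_peak), c(0.04, 5, 140, 30))
  expect_equal(neuron_params("CH")$c, -50)
  expect_equal(neuron_params("FS")$a, 0.1)
  expect_equal(neuron_params("LTS")$b, 0.25)
  # shared voltage-equation constants across classes
  for (lbl in c("CH", "FS", "LTS")) {
    q <- neuron_params(lbl)
    expect_equal(
      c(q$alpha, q$beta, q$gamma, q$v_peak),
      c(p$alpha, p$beta, p$gamma, p$v_peak)
    )
    expect_gt(q$b, q$a) # subcritical-Hopf condition
  }
})

test_that("derivatives match hand-computed values", {
  RS <- neuron_params("RS")
  # -70 is the stable root of 0.04 v^2 + 4.8 v + 140 = 0
  expect_equal(derivatives(-70, -14, 0, RS), c(dv_dt = 0, du_dt = 0),
    tolerance = 1e-12
  )
  # at v = u = I = 0 only the constant term remains
  expect_equal(derivatives(0, 0, 0, RS)[["dv_dt"]], 140)
  # LTS rest: left root of 0.04 v^2 + 4.75 v + 140 = 0 (root-finder oracle)
  LTS <- neuron_params("LTS")
  v_root <- uniroot(
    function(v) 0.04 * v^2 + 4.75 * v + 140,
    c(-70, -62), tol = 1e-12
  )$root
  expect_equal(v_root, -64.414, tolerance = 1e-4)
  d <- derivatives(v_root, LTS$b * v_root, 0, LTS)
  expect_lt(abs(d[["dv_dt"]]), 1e-9)
  expect_equal(d[["du_dt"]], 0)
  expect_error(derivatives(NaN, 0, 0, RS), "non-finite")
})

test_that("fire-and-reset rule sets v to c and increments u by d", {
  expect_equal(
    apply_reset(30, 5, neuron_params("RS")),
    c(v = -65, u = 13)
  )
  expect_equal(
    apply_reset(30, 0, neuron_params("CH")),
    c(v = -50, u = 2)
  )
  # rule applies for any v at or above the cutoff
  expect_equal(
    apply_reset(31.7, -3, neuron_params("FS")),
    c(v = -65, u = -1)
  )
  expect_error(apply_reset(0, 0, neuron_params("RS")), "v_peak")
})

test_that("resting states solve the nullcline intersection", {
  RS <- neuron_params("RS")
  expect_equal(resting_state(RS, 0), c(v = -70, u = -14))
  # at the saddle-node current the two equilibria merge at (b - beta)/(2 alpha)
  I_sn <- critical_currents(RS)$I_sn
  expect_equal(resting_state(RS, I_sn)[["v"]], -60)
  # above it no rest state exists
  expect_null(resting_state(RS, 10))
  # all four classes: derivatives vanish at rest
  for (lbl in c("RS", "CH", "FS", "LTS")) {
    p <- neuron_params(lbl)
    r <- resting_state(p, 0)
    d <- derivatives(r[["v"]], r[["u"]], 0, p)
    expect_lt(max(abs(d)), 1e-10)
  }
  # LTS rests above (less negative than) RS: larger b
  expect_gt(
    resting_state(neuron_params("LTS"))[["v"]],
    resting_state(neuron_params("RS"))[["v"]]
  )
})

test_that("critical currents match the closed forms and their ordering", {
  RS <- neuron_params("RS")
  cc <- critical_currents(RS)
  expect_equal(cc$I_sn, 4.8^2 / 0.16 - 140) # = 4
  expect_equal(cc$I_sn, 4)
  expect_equal(cc$I_H, (23.04 - 0.0324) / 0.16 - 140, tolerance = 1e-12)
  expect_equal(critical_currents(neuron_params("LTS"))$I_sn, 1.015625)
  # LTS ignites at weaker current than RS
  expect_lt(
    critical_currents(neuron_params("LTS"))$I_sn,
    critical_currents(neuron_params("RS"))$I_sn
  )
  for (lbl in c("RS", "CH", "FS", "LTS")) {
    cc <- critical_currents(neuron_params(lbl))
    expect_lt(cc$I_H, cc$I_sn) # b > a for every class
  }
})

test_that("nullclines shift pointwise with the input current", {
  RS <- neuron_params("RS")
  grid <- seq(-80, -50, by = 0.5)
  nl0 <- nullclines(RS, 0, grid)
  expect_equal(
    nl0$u_bar[grid == -70], nl0$u_star[grid == -70],
    tolerance = 1e-12
  )
  nl3 <- nullclines(RS, 3, grid)
  expect_equal(nl3$u_bar, nl0$u_bar + 3)
  expect_error(nullclines(RS, 0, numeric(0)), "empty")
})

test_that("AdEx rest state lies near the Izhikevich rest", {
  for (lbl in c("RS", "FS")) {
    izh <- resting_state(neuron_params(lbl))
    adex <- resting_state(neuron_params(lbl, model_kind = "adex"))
    expect_false(is.null(adex))
    expect_lt(abs(adex[["v"]] - izh[["v"]]), 5)
    # it is a genuine fixed point of the adex field
    d <- derivatives(adex[["v"]], adex[["u"]], 0,
      neuron_params(lbl, model_kind = "adex")
    )
    expect_lt(max(abs(d)), 1e-8)
  }
})

test_that("closed-form thresholds agree with numeric bifurcation detection", {
  for (lbl in c("RS", "CH", "FS", "LTS")) {
    p <- neuron_params(lbl)
    cc <- critical_currents(p)
    # saddle-node: the current at which the minimum of the folded field
    # alpha v^2 + (beta - b) v + gamma + I crosses zero
    g_min <- function(I) {
      optimize(function(v) p$alpha * v^2 + (p$beta - p$b) * v + p$gamma + I,
        c(-120, 0)
      )$objective
    }
    I_sn_num <- uniroot(g_min, c(-50, 50), tol = 1e-10)$root
    expect_lt(abs(I_sn_num - cc$I_sn) / abs(cc$I_sn), 0.01)
    # Hopf: trace of the Jacobian at the stable equilibrium crosses zero
    tr_at <- function(I) {
      r <- resting_state(p, I)
      if (is.null(r)) {
        return(NA_real_)
      }
      2 * p$alpha * r[["v"]] + p$beta - p$a
    }
    I_H_num <- uniroot(tr_at, c(-50, cc$I_sn - 1e-9), tol = 1e-10)$root
    expect_lt(abs(I_H_num - cc$I_H) / abs(cc$I_H), 0.01)
  }
})
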
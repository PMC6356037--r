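test_that("UV rules: ~370 nm penta, 420-430 nm ambiguous, both mixed", {
  expect_equal(infer_from_uv(370)$verdict, "penta")
  expect_equal(infer_from_uv(377)$verdict, "penta")   # within +-8 nm
  expect_equal(infer_from_uv(425)$verdict, "ambiguous")
  expect_equal(infer_from_uv(c(370, 425))$verdict, "mixed")
  expect_equal(infer_from_uv(400)$verdict, "undetermined")
  expect_equal(infer_from_uv(numeric(0))$verdict, "undetermined")
  expect_error(infer_from_uv(250), "300-800")
})

test_that("rRaman rules: ~1491 penta (hemin caveat), ~1505 hexa, both mixed", {
  call <- infer_from_rraman(1491)
  expect_equal(call$verdict, "penta")
  expect_match(call$caveats, "hemin")
  expect_equal(infer_from_rraman(1505)$verdict, "hexa")
  expect_equal(infer_from_rraman(c(1491, 1505))$verdict, "mixed")
  expect_equal(infer_from_rraman(1450)$verdict, "undetermined")
  expect_error(infer_from_rraman(1200), "1400-1600")
})

test_that("EPR rules: g~6 + g~2 penta, three g in 1.5-3 hexa", {
  expect_equal(infer_from_epr(c(2.0, 6.0))$verdict, "penta")
  expect_equal(infer_from_epr(c(1.8, 2.2, 2.9))$verdict, "hexa")
  expect_equal(infer_from_epr(numeric(0))$verdict, "undetermined")
  expect_equal(infer_from_epr(4.5)$verdict, "undetermined")
  # two values in the low-spin range are not enough for a hexa call
  expect_equal(infer_from_epr(c(1.8, 2.5))$verdict, "undetermined")
  expect_error(infer_from_epr(0.1), "0.5-10")
})

test_that("combine_evidence resolves, conflicts and passes unanimity through", {
  expect_equal(combine_evidence(list(infer_from_uv(370),
                                     infer_from_rraman(1491)))$verdict, "penta")
  # ambiguous UV resolved by a decisive technique
  call <- combine_evidence(list(infer_from_uv(425), infer_from_epr(c(1.8, 2.2, 2.9))))
  expect_equal(call$verdict, "hexa")
  # penta/hexa conflict -> mixed with a conflict flag
  call <- combine_evidence(list(infer_from_rraman(1491),
                                infer_from_epr(c(1.8, 2.2, 2.9))))
  expect_equal(call$verdict, "mixed")
  expect_true(any(grepl("conflict", call$evidence$rule)))
  # lone ambiguous stays ambiguous; nothing matched -> undetermined
  expect_equal(combine_evidence(list(infer_from_uv(425)))$verdict, "ambiguous")
  expect_equal(combine_evidence(list(infer_from_uv(500)))$verdict, "undetermined")
  expect_error(combine_evidence(list()), "no partial")
})

test_that("the combined verdict is invariant to partial order", {
  partials <- list(infer_from_uv(c(370, 425)), infer_from_rraman(1505),
                   infer_from_epr(c(2.0, 6.0)))
  ref <- combine_evidence(partials)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(combine_evidence(partials[perm])$verdict, ref$verdict)
    expect_equal(combine_evidence(partials[perm])$uv_group, ref$uv_group)
  }
})

test_that("UV-group labels follow the documented interpretation", {
  expect_equal(coordination_call(soret_maxima_nm = 370)$uv_group, "I")
  expect_equal(coordination_call(soret_maxima_nm = 425)$uv_group, "II")
  expect_equal(coordination_call(soret_maxima_nm = c(370, 425))$uv_group, "III")
  expect_equal(coordination_call(soret_maxima_nm = 500)$uv_group, "IV")
  expect_equal(coordination_call(nu3_wavenumbers_cm1 = 1491)$uv_group, "none")
})

test_that("widening tolerances never flips penta <-> hexa", {
  set.seed(109)
  base <- spectro_tolerances()
  wide <- base
  wide$soret_penta_tol_nm <- base$soret_penta_tol_nm * 2
  wide$nu3_tol_cm1 <- base$nu3_tol_cm1 * 2
  wide$g_tol <- base$g_tol * 2
  for (i in 1:100) {
    nu3 <- runif(1, 1400, 1600)
    v1 <- infer_from_rraman(nu3, base)$verdict
    v2 <- infer_from_rraman(nu3, wide)$verdict
    if (v1 != "undetermined") {
      expect_true(v2 %in% c(v1, "mixed"))
    }
    soret <- runif(1, 300, 800)
    u1 <- infer_from_uv(soret, base)$verdict
    u2 <- infer_from_uv(soret, wide)$verdict
    if (u1 != "undetermined") expect_true(u2 %in% c(u1, "mixed"))
  }
})

test_that("the engine is total: always a verdict on in-range inputs", {
  set.seed(110)
  for (i in 1:50) {
    call <- coordination_call(
      soret_maxima_nm = runif(sample(0:2, 1), 300, 800),
      nu3_wavenumbers_cm1 = runif(sample(0:2, 1), 1400, 1600),
      epr_g_values = runif(sample(0:3, 1), 0.5, 10))
    expect_true(call$verdict %in% c("penta", "hexa", "mixed", "ambiguous",
                                    "undetermined"))
    # undetermined iff no technique matched a rule
    matched <- call$evidence$verdict[call$evidence$technique != "combined"]
    expect_equal(call$verdict == "undetermined",
                 all(matched == "undetermined"))
  }
})
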
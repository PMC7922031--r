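test_that("packaged carbamazepine model carries the published values", {
  cbz <- carbamazepine_model()
  expect_equal(cbz$molecular_weight, 236.27)
  expect_equal(cbz$lipophilicity, 2.00)
  expect_equal(cbz$solubility, 336)
  expect_equal(cbz$fraction_unbound, 0.25)
  expect_equal(cbz$intestinal_permeability, 4.3e-4)
  get <- function(lbl) Filter(function(p) identical(p$label, lbl),
                              cbz$processes)[[1]]
  p1 <- get("CYP3A4->CBZ-E")
  expect_equal(c(p1$K_m, p1$k_cat), c(248, 0.75))
  p2 <- get("CYP2C8->CBZ-E")
  expect_equal(c(p2$K_m, p2$k_cat), c(757, 0.67))
  p3 <- get("CYP3A4-OH")
  expect_equal(c(p3$K_m, p3$k_cat), c(282, 0.20))
  p4 <- get("CYP2B6")
  expect_equal(c(p4$K_m, p4$k_cat), c(420, 0.43))
  p5 <- get("UGT2B7")
  expect_equal(p5$K_m, 214)
  expect_equal(p5$k_cat, 9.53e-3, tolerance = 5e-4)
  expect_equal(get("CL_hep")$CL_hep, 0.02)
  expect_equal(get("GFR")$gfr_fraction, 0.03)
  emax <- sapply(cbz$interactions, function(a) a$E_max)
  names(emax) <- sapply(cbz$interactions, function(a) a$target_enzyme)
  expect_equal(emax[["CYP3A4"]], 6.00)
  expect_equal(emax[["CYP2B6"]], 17.00)
  expect_equal(emax[["EPHX1"]], 3.25)
  expect_true(all(sapply(cbz$interactions, function(a) a$EC_50) == 20.0))
})

test_that("packaged epoxide model carries the published values", {
  cbze <- carbamazepine_epoxide_model()
  expect_equal(cbze$molecular_weight, 252.27)
  expect_equal(cbze$lipophilicity, 1.00)
  expect_equal(cbze$fraction_unbound, 0.518)
  expect_equal(cbze$intestinal_permeability, 5.0e-3)
  kinds <- vapply(cbze$processes, `[[`, character(1), "kind")
  expect_setequal(kinds, c("specific_cl", "gfr"))
  ep <- cbze$processes[[which(kinds == "specific_cl")]]
  expect_equal(ep$enzyme, "EPHX1")
  expect_equal(ep$CL_spec, 0.01)
  expect_equal(cbze$processes[[which(kinds == "gfr")]]$gfr_fraction, 0.21)
  # independently administrable: has an oral solution formulation
  expect_true("solution" %in% names(cbze$formulations))
})

test_that("pathway inventory and parent-metabolite links match the scheme", {
  cbz <- carbamazepine_model()
  kinds <- vapply(cbz$processes, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "mm"), 5L)
  expect_equal(sum(kinds == "hepatic_cl"), 1L)
  expect_equal(sum(kinds == "gfr"), 1L)
  enzymes <- vapply(cbz$processes[kinds == "mm"], `[[`, character(1),
                    "enzyme")
  expect_equal(sort(enzymes),
               sort(c("CYP3A4", "CYP3A4", "CYP2C8", "CYP2B6", "UGT2B7")))
  # exactly the two epoxide-forming pathways carry a metabolite link
  linked <- Filter(function(p) !is.null(p$product), cbz$processes)
  expect_length(linked, 2L)
  expect_setequal(vapply(linked, `[[`, character(1), "enzyme"),
                  c("CYP3A4", "CYP2C8"))
  expect_equal(metabolite_links(cbz), "carbamazepine-10,11-epoxide")
  expect_null(metabolite_links(carbamazepine_epoxide_model()))
})

test_that("serialization round-trip is the identity for packaged models", {
  for (build in list(carbamazepine_model, carbamazepine_epoxide_model)) {
    drug <- build()
    path <- tempfile(fileext = ".json")
    write_drug_config(drug, path)
    back <- load_drug_config(path)
    expect_equal(back, drug)
    unlink(path)
  }
})

test_that("drug config schema rejects malformed input", {
  cbz <- carbamazepine_model()
  path <- tempfile(fileext = ".json")
  write_drug_config(cbz, path)
  x <- jsonlite::read_json(path)

  bad <- x; bad$unexpected_key <- 1
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, p2, auto_unbox = TRUE, null = "null")
  expect_error(load_drug_config(p2), "unexpected_key")

  bad <- x; bad$processes[[1]]$K_m <- -1
  jsonlite::write_json(bad, p2, auto_unbox = TRUE, null = "null")
  expect_error(load_drug_config(p2), "K_m")

  bad <- x; bad$processes[[1]]$enzyme <- "CYP0X0"
  jsonlite::write_json(bad, p2, auto_unbox = TRUE, null = "null")
  expect_error(load_drug_config(p2), "CYP0X0")

  bad <- x; bad$fraction_unbound <- 1.7
  jsonlite::write_json(bad, p2, auto_unbox = TRUE, null = "null")
  expect_error(load_drug_config(p2), "fraction_unbound")
  unlink(c(path, p2))
})

test_that("interaction constructors enforce mode-specific fields", {
  a <- action_mbi("CYP3A4", K_I = 10, k_inact = 0.05)
  expect_equal(a$mode, "mechanism-based")
  expect_true(all(c("K_I", "k_inact") %in% names(a)))
  expect_false("K_i" %in% names(a))
  b <- action_competitive_inhibition("CYP3A4", K_i = 4)
  expect_equal(b$mode, "competitive")
  expect_false(any(c("K_I", "k_inact") %in% names(b)))
  expect_error(action_mbi("CYP3A4", K_I = -1, k_inact = 0.05), "K_I")
  expect_error(action_induction("NOPE", 20, 6), "NOPE")
})

test_that("packaged synthetic perpetrator stubs load and validate", {
  dir <- system.file("extdata", "perpetrators", package = "pbpkddi")
  files <- list.files(dir, full.names = TRUE)
  expect_length(files, 5L)
  for (f in files) {
    d <- load_drug_config(f)
    expect_s3_class(d, "drug_parameters")
    expect_match(d$name, "synthetic")   # placeholder values, flagged
  }
  ery <- load_drug_config(file.path(dir, "erythromycin_synthetic.json"))
  mb <- Filter(function(a) a$mode == "mechanism-based", ery$interactions)
  expect_length(mb, 1L)
  expect_true(all(c("K_I", "k_inact") %in% names(mb[[1]])))
})

test_that("at most one GFR process is allowed", {
  expect_error(drug_parameters("x", 100, 1, 100, 0.5, 1e-4,
                               processes = list(process_gfr(0.1),
                                                process_gfr(0.2))),
               "GFR")
})
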
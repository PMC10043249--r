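test_that("default schema matches the extraction protocol", {
  sch <- default_schema()
  expect_length(sch$specs, 8L)
  expect_identical(raw_feature_count(sch), 30L)
  # determinism
  expect_identical(default_schema(), sch)
  # monitor-unit spec: per-field MU on all four fields
  mu <- Filter(function(s) s$name == "meterset", sch$specs)[[1]]
  expect_identical(mu$unit, "MU")
  expect_identical(mu$field_group, "both")
  expect_identical(mu$per_field_count, 4L)
  # column layout is <feature>_f<k>
  expect_identical(schema_columns(sch)[1:3], c("segments_f1", "segments_f2",
                                               "ssd_f1"))
})

test_that("feature_spec enforces its invariants", {
  expect_error(feature_spec("x", per_field_count = 0), "positive")
  expect_error(feature_spec("seg", value_kind = "categorical",
                            levels = "only_one"), ">= 2")
  expect_error(feature_spec("mu", value_kind = "continuous",
                            levels = c("a", "b")), "must not declare")
  expect_error(feature_schema(list(feature_spec("a"), feature_spec("a"))),
               "unique")
})

test_that("plan tables load from CSV and JSON with labels mapped", {
  tab <- tiny_table(3)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_plan_table(tab, csv)
  back <- load_plan_table(csv, tiny_schema())
  expect_equal(back$data, tab$data, tolerance = 1e-12)
  expect_null(back$labels)

  # labelled round trip through 0/1 column
  lab <- c("normal", "abnormal", "normal")
  tab2 <- tiny_table(3, labels = lab)
  csv2 <- withr::local_tempfile(fileext = ".csv")
  write_plan_table(tab2, csv2)
  expect_true(any(grepl("is_abnormal", readLines(csv2)[1])))
  back2 <- load_plan_table(csv2, tiny_schema())
  expect_identical(as.character(back2$labels), lab)

  json <- withr::local_tempfile(fileext = ".json")
  write_plan_table(tab2, json, format = "json")
  back3 <- load_plan_table(json, tiny_schema())
  expect_identical(as.character(back3$labels), lab)
  expect_equal(back3$data$mu_f1, tab2$data$mu_f1, tolerance = 1e-9)
})

test_that("schema mismatch and bad categories fail loudly with locations", {
  tab <- tiny_table(3)
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- tab$data
  df$mu_f2 <- NULL
  utils::write.csv(df, csv, row.names = FALSE)
  expect_error(load_plan_table(csv, tiny_schema()),
               class = "planomaly_schema_mismatch")
  expect_error(load_plan_table(csv, tiny_schema()), "mu_f2")

  df2 <- tab$data
  df2$mode_f1[2] <- "electron"   # unseen category must surface loudly
  csv2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, csv2, row.names = FALSE)
  err <- expect_error(load_plan_table(csv2, tiny_schema()),
                      class = "planomaly_validation_error")
  expect_match(conditionMessage(err), "mode_f1")
  expect_match(conditionMessage(err), "electron")
  expect_match(conditionMessage(err), "2")
})

test_that("one_hot_encode places a single 1 at the level index", {
  expect_identical(one_hot_encode("tangent", c("IMRT", "tangent")),
                   c(0L, 1L))
  expect_identical(one_hot_encode("IMRT", c("IMRT", "tangent")),
                   c(1L, 0L))
  levels <- letters[1:5]
  for (k in seq_along(levels)) {
    v <- one_hot_encode(levels[k], levels)
    expect_identical(sum(v), 1L)
    expect_identical(which(v == 1L), k)
  }
  expect_error(one_hot_encode("x", levels),
               class = "planomaly_validation_error")
})

test_that("encode_table expands to the schema-derived width with a consistent mask", {
  tab <- tiny_table(6)
  em <- encode_table(tab, scale = "none")
  # 2 continuous + 2 blocks of 2 levels
  expect_identical(n_dims(em), 6L)
  expect_identical(sum(em$mask$kind == "binary"), 4L)
  expect_identical(sum(em$mask$kind == "continuous"), 2L)
  # one-hot block rows sum to 1, binary cells are 0/1
  bin <- em$values[, em$mask$kind == "binary"]
  expect_true(all(bin %in% c(0, 1)))
  blocks <- split(seq_len(nrow(em$mask)),
                  paste(em$mask$feature, em$mask$slot))
  for (jj in blocks) {
    if (all(em$mask$kind[jj] == "binary")) {
      expect_true(all(rowSums(em$values[, jj, drop = FALSE]) == 1))
    }
  }
  # width is invariant to row count/order
  em2 <- encode_table(tiny_table(3), scale = "none")
  expect_identical(n_dims(em2), 6L)
  expect_error(encode_table(plan_table(tab$data[0, ], tiny_schema())),
               "empty")
})

test_that("illustrative widths: 26 continuous + 4x8 categorical give 58 dims", {
  specs <- c(
    lapply(1:26, function(i) feature_spec(paste0("c", i), "both", 1L)),
    lapply(1:4, function(i) feature_spec(paste0("k", i), "both", 1L,
                                         "categorical",
                                         levels = as.character(1:8))))
  tabdata <- as.data.frame(c(
    stats::setNames(lapply(1:26, function(i) rnorm(3)),
                    paste0("c", 1:26, "_f1")),
    stats::setNames(lapply(1:4, function(i)
      sample(as.character(1:8), 3, TRUE)), paste0("k", 1:4, "_f1"))))
  em <- encode_table(plan_table(tabdata, feature_schema(specs)),
                     scale = "none")
  expect_identical(n_dims(em), 58L)
  # all-continuous schema has identity width
  em2 <- encode_table(plan_table(tabdata[, 1:26],
                                 feature_schema(specs[1:26])),
                      scale = "none")
  expect_identical(n_dims(em2), 26L)
  expect_true(all(em2$mask$kind == "continuous"))
})

test_that("minmax scaling and its inverse are exact", {
  sch <- feature_schema(list(feature_spec("d", "both", 1L, unit = "MU")))
  tab <- plan_table(data.frame(d_f1 = c(100, 110, 120)), sch)
  em <- encode_table(tab, scale = "minmax")
  expect_equal(as.numeric(em$values[, "d_f1"]), c(0, 0.5, 1))
  p <- em$scaler$params
  expect_equal(p$center[p$column == "d_f1"], 100)
  expect_equal(p$scale[p$column == "d_f1"], 20)
  back <- decode_table(em)
  expect_equal(back$data$d_f1, c(100, 110, 120), tolerance = 1e-12)
})

test_that("round trip: arg-max decoding recovers every categorical value", {
  tab <- small_benchmark()$table
  for (scale in c("minmax", "none")) {
    em <- encode_table(tab, scale = scale)
    back <- decode_table(em)
    expect_equal(back$data, tab$data, tolerance = 1e-9)
    if (scale == "minmax") {
      cont <- em$values[, em$mask$kind == "continuous"]
      expect_true(all(cont >= 0 & cont <= 1))
    }
  }
})

test_that("constant continuous column under zscore passes through with warning", {
  sch <- feature_schema(list(feature_spec("d", "both", 1L)))
  tab <- plan_table(data.frame(d_f1 = rep(5, 4)), sch)
  expect_warning(em <- encode_table(tab, scale = "zscore"), "constant")
  expect_equal(as.numeric(em$values[, 1]), rep(5, 4))
})

test_that("schema serialization round-trips", {
  sch <- default_schema()
  path <- withr::local_tempfile(fileext = ".json")
  write_schema(sch, path)
  expect_identical(read_schema(path), sch)
})
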
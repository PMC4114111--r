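make_dict <- function() {
  data.frame(name = c("id", "diagnosis", "age", "rt"),
             label = "", kind = c("identifier", "factor", "numeric",
                                  "numeric"),
             units = "", source = "t", stringsAsFactors = FALSE)
}

write_csv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("loading cleans declared columns and logs every altered cell", {
  path <- write_csv_fixture(c("id,diagnosis,age,rt",
                              "s1,control,30,512.5",
                              "s2,control,NA,433",
                              "s3,SZ,45,abc"))
  tab <- load_table(path, make_dict())
  expect_equal(n_subjects(tab), 3L)
  expect_equal(sum(is.na(tab$data$age)), 1L)
  expect_equal(sum(is.na(tab$data$rt)), 1L)
  log <- tab$provenance$cleaning_log
  expect_equal(nrow(log), 2L)
  expect_setequal(log$action, c("missing-code", "unparseable"))
  expect_equal(log$subject[log$action == "unparseable"], "s3")
})

test_that("hard range limits in the cleaning policy set cells missing", {
  path <- write_csv_fixture(c("id,diagnosis,age,rt",
                              "s1,control,30,100000",
                              "s2,SZ,31,400"))
  tab <- load_table(path, make_dict(),
                    cleaning_policy(ranges = list(rt = c(0, 5000))))
  expect_true(is.na(tab$data$rt[1]))
  expect_equal(tab$data$rt[2], 400)
  expect_equal(tab$provenance$cleaning_log$action, "out-of-range")
})

test_that("structural load errors are rejected", {
  ragged <- write_csv_fixture(c("id,diagnosis,age,rt", "s1,control,30",
                                "s2,SZ,31,400"))
  expect_error(load_table(ragged, make_dict()), "ragged",
               class = "viva_load_error")
  dup <- write_csv_fixture(c("id,diagnosis,age,rt", "s1,control,30,1",
                             "s1,SZ,31,2"))
  expect_error(load_table(dup, make_dict()), "duplicate",
               class = "viva_load_error")
  extra <- write_csv_fixture(c("id,diagnosis,age,rt,mystery",
                               "s1,control,30,1,9"))
  expect_error(load_table(extra, make_dict()), "mystery",
               class = "viva_load_error")
  expect_warning(tab <- load_table(extra, make_dict(), permissive = TRUE),
                 class = "viva_load_warning")
  expect_false("mystery" %in% names(tab$data))
})

test_that("load -> write -> load round-trips the table", {
  tab <- make_random_table(25, 6, missing_rate = 0.2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tab, path)
  back <- load_table(path, tab$dictionary)
  expect_equal(back$data, tab$data)
  expect_identical(back$subject_ids, tab$subject_ids)
})

test_that("subsets filter exactly, exclude missing, and are idempotent", {
  path <- write_csv_fixture(c(
    "id,diagnosis,age,rt",
    paste0("s", 1:15, ",", c(rep("control", 10), rep("SZ", 5)), ",",
           c(25, NA, 30:42), ",500")))
  tab <- load_table(path, make_dict())
  controls <- list(predicate = list(
    list(attribute = "diagnosis", op = "=", value = "control")))
  s1 <- apply_subset(tab, controls)
  expect_equal(n_subjects(s1), 10L)
  expect_identical(apply_subset(s1, controls)$data, s1$data)

  adults <- list(predicate = list(
    list(attribute = "age", op = ">=", value = 21)))
  s2 <- apply_subset(tab, adults)
  expect_false("s2" %in% s2$subject_ids)  # missing age excluded
  expect_equal(n_subjects(s2), 14L)

  expect_identical(apply_subset(tab, list(predicate = list()))$data,
                   tab$data)
  expect_error(apply_subset(tab, list(predicate = list(
    list(attribute = "nope", op = "=", value = 1)))),
    class = "viva_resolve_error")
  # subsetting never adds subjects; order preserved
  expect_true(all(s1$subject_ids %in% tab$subject_ids))
  expect_identical(s1$subject_ids,
                   tab$subject_ids[tab$subject_ids %in% s1$subject_ids])
})

test_that("discretization uses left-open right-closed decade intervals", {
  edges <- c(20, 30, 40)
  labels <- c("21-30", "31-40")
  expect_identical(discretize(c(30, 31, 15, 20, 40.5, NA), edges, labels),
                   c("21-30", "31-40", NA, "21-30", NA, NA))
  expect_error(discretize(1, c(20, 20, 40), labels),
               class = "viva_config_error")
  expect_error(discretize(1, edges, "only-one"),
               class = "viva_config_error")
})

test_that("group assignment partitions subjects and reports counts", {
  tab <- make_random_table(60, 3, missing_rate = 0, seed = 7)
  a <- assign_groups(tab, grp_grouping())
  expect_identical(a$levels, c("A", "B", "C"))
  expect_equal(sum(a$counts) + sum(is.na(a$assignment)), 60L)
  expect_equal(unname(a$counts["A"]), sum(tab$data$grp == "A"))

  # binned grouping: missing source value -> unassigned
  dict <- rbind(as.data.frame(tab$dictionary),
                data.frame(name = "age", label = "", kind = "numeric",
                           units = "", source = "test"))
  d2 <- tab$data
  d2$age <- c(NA, runif(59, 21, 90))
  t2 <- visova:::new_phenotype_table(d2, dict)
  g <- list(name = "Age", derivation = "bins", source_variable = "age",
            edges = seq(20, 90, 10),
            labels = c("21-30", "31-40", "41-50", "51-60", "61-70",
                       "71-80", "81-90"))
  a2 <- assign_groups(t2, g)
  expect_true(is.na(a2$assignment[1]))
  expect_equal(sum(a2$counts), 59L)
  d25 <- which(abs(d2$age - 25) == min(abs(d2$age - 25), na.rm = TRUE))[1]
  if (d2$age[d25] > 21 && d2$age[d25] <= 30)
    expect_identical(a2$assignment[d25], "21-30")

  # union grouping with overlapping levels is a configuration error
  gu <- list(name = "bad", derivation = "union", levels = list(
    low = list(list(attribute = "v01", op = "<", value = 1)),
    all = list()))
  expect_error(assign_groups(tab, gu), "more than one level",
               class = "viva_config_error")
})

test_that("groups configuration round-trips through JSON", {
  cfg <- list(
    subsets = list(ctrl = list(predicate = list(
      list(attribute = "diagnosis", op = "=", value = "control")))),
    groupings = list(Age = list(derivation = "bins",
                                source_variable = "age",
                                edges = seq(20, 90, 10),
                                labels = paste0("L", 1:7))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  got <- read_groups_config(path)
  expect_identical(names(got$subsets), "ctrl")
  expect_identical(got$groupings$Age$labels, paste0("L", 1:7))
  expect_error(read_groups_config(list(groupings = list(
    bad = list(derivation = "bins", source_variable = "x",
               edges = c(3, 2, 1), labels = c("a", "b"))))),
    class = "viva_config_error")
})
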
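fake_roster <- function(n_f, n_m) {
  tibble::tibble(
    individual_key = c(sprintf("F%02d|BML|F|large", seq_len(n_f)),
                       sprintf("M%02d|BML|M|large", seq_len(n_m))),
    sex = rep(c("F", "M"), c(n_f, n_m))
  )
}

test_that("default draws leave 14 training individuals of each sex from 22 + 22", {
  a <- assign_splits(fake_roster(22, 22), seed = 3)
  tab <- table(a$sex, a$split)
  expect_identical(as.vector(tab["F", ]), c(14L, 4L, 4L))
  expect_identical(as.vector(tab["M", ]), c(14L, 4L, 4L))
  expect_identical(sum(tab[, "train"]), 28L)
  # every individual in exactly one split
  expect_identical(anyDuplicated(a$individual_key), 0L)
})

test_that("zero-sized draws put everyone in train; shortages error", {
  a <- assign_splits(fake_roster(5, 5), n_val_per_sex = 0, n_test_per_sex = 0)
  expect_true(all(a$split == "train"))
  expect_error(assign_splits(fake_roster(8, 8), n_val_per_sex = 4,
                             n_test_per_sex = 4), "Insufficient")
})

test_that("assignments are seed-deterministic and seed-sensitive", {
  r <- fake_roster(6, 6)
  a1 <- assign_splits(r, n_val_per_sex = 1, n_test_per_sex = 1, seed = 1)
  a2 <- assign_splits(r, n_val_per_sex = 1, n_test_per_sex = 1, seed = 1)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  # over several seeds at least one assignment must differ (30x30 possible
  # val/test draws per sex make a collision across all pairs implausible)
  others <- lapply(2:6, function(s) {
    assign_splits(r, n_val_per_sex = 1, n_test_per_sex = 1, seed = s)$split
  })
  expect_true(any(vapply(others, function(s) !identical(s, a1$split), logical(1))))
})

test_that("check_leakage counts split-crossing individuals exactly", {
  man <- tiny_manifest(n_per_sex = 5, seed = 21)
  a <- assign_splits(roster_from_manifest(man), n_val_per_sex = 1,
                     n_test_per_sex = 1, seed = 2)
  expect_identical(check_leakage(a, man)$n_leaked, 0L)
  # adversarial: one individual listed under two splits
  bad <- dplyr::bind_rows(a, dplyr::mutate(a[1, ], split = factor("test", levels(a$split))))
  audit <- check_leakage(bad, man)
  expect_identical(audit$leaked_individuals, a$individual_key[1])
  # frame-level random split: leaked count equals brute-force intersection
  key <- paste(man$individual_id, man$location, man$sex, man$size_class, sep = "|")
  idx <- withr::with_seed(9, sample(nrow(man), round(0.8 * nrow(man))))
  fake <- tibble::tibble(
    individual_key = c(key[idx], key[-idx]),
    split = factor(rep(c("train", "test"), c(length(idx), nrow(man) - length(idx))),
                   levels = c("train", "val", "test"))
  )
  audit2 <- check_leakage(fake, man)
  expect_identical(sort(audit2$leaked_individuals),
                   sort(intersect(unique(key[idx]), unique(key[-idx]))))
  expect_error(check_leakage(a[-1, ], man), "absent")
})

test_that("balancing tops up under-represented individuals without touching originals", {
  man <- tiny_manifest(n_per_sex = 3, frames = c(2L, 5L), seed = 31)
  counts <- table(paste(man$individual_id, man$sex))
  bal <- balance_training_set(man, target = max(counts), seed = 1)
  after <- table(paste(bal$individual_id, bal$sex))
  expect_true(all(after == max(counts)))
  expect_identical(sum(bal$synthetic), as.integer(sum(max(counts) - counts)))
  # originals survive verbatim
  expect_true(all(man$path %in% bal$path[!bal$synthetic]))
  # closed-form output size, with a cap
  cap <- 4L
  bal2 <- balance_training_set(man, target = 10, cap = cap, seed = 1)
  expect_identical(nrow(bal2), as.integer(sum(pmax(counts, cap))))
  # auto target on already-balanced input adds nothing
  even <- tiny_manifest(n_per_sex = 2, frames = c(3L, 3L), seed = 32)
  expect_identical(sum(balance_training_set(even, seed = 1)$synthetic), 0L)
  expect_error(balance_training_set(even[0, ]), "Empty")
})

test_that("augmented rows stay inside the training split", {
  man <- tiny_manifest(n_per_sex = 4, seed = 33)
  a <- assign_splits(roster_from_manifest(man), n_val_per_sex = 1,
                     n_test_per_sex = 1, seed = 3)
  fr <- apply_splits(man, a)
  train <- dplyr::filter(fr, split == "train")
  bal <- balance_training_set(train, target = 6, seed = 4)
  bal_keys <- unique(paste(bal$individual_id, bal$location, bal$sex,
                           bal$size_class, sep = "|"))
  train_keys <- a$individual_key[a$split == "train"]
  expect_true(all(bal_keys %in% train_keys))
})
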
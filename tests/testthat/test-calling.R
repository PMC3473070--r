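# One shared small run for the calling tests (fitted once per file).
.calling_fixture <- local({
  r <- small_separated_run(n = 4000, seed = 27)
  fit <- em_fit(r$h, nseg = r$nseg)
  calls <- call_genotypes(r$tt, fit, r$h)
  list(r = r, fit = fit, calls = calls)
})

test_that("every SNP gets its bin's probability triple and the argmax call", {
  fx <- .calling_fixture
  calls <- fx$calls
  expect_equal(nrow(calls), nrow(fx$r$tt))
  s <- calls$p_AA + calls$p_AB + calls$p_BB
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-9)
  expect_gte(min(calls$pstar), 1 / 3)
  expect_false(any(calls$call == "NN"))
  idx <- cbind(seq_len(nrow(calls)),
               match(calls$call, c("AA", "AB", "BB")))
  pm <- as.matrix(calls[, c("p_AA", "p_AB", "p_BB")])
  expect_equal(pm[idx], calls$pstar)
  # spot-check one SNP against membership_at
  k <- 123L
  m <- membership_at(fx$fit, fx$r$h$bin_index[k, 1], fx$r$h$bin_index[k, 2])
  expect_equal(unname(m$p), unname(pm[k, ]))
})

test_that("calls on a well-separated array match the generating genotypes", {
  fx <- .calling_fixture
  expect_gte(mean(fx$calls$call == fx$r$sim$truth$genotype), 0.995)
})

test_that("exact probability ties resolve to AB then AA, deterministically", {
  am <- arraycall:::argmax_call(c(1, 1, 0.2) / 3, c(1, 1, 0.2) / 3,
                                c(0.5, 1, 0.2) / 3)
  expect_equal(am$call, c("AB", "AB", "AB"))
  expect_equal(am$tie, c(TRUE, TRUE, TRUE))
  am2 <- arraycall:::argmax_call(0.45, 0.1, 0.45)
  expect_equal(am2$call, "AA")        # AA preferred over BB at a tie
  expect_true(am2$tie)
  am3 <- arraycall:::argmax_call(0.2, 0.5, 0.3)
  expect_equal(am3$call, "AB")
  expect_false(am3$tie)
})

test_that("the NoCall threshold is optional, monotone and idempotent", {
  fx <- .calling_fixture
  calls <- fx$calls
  expect_identical(apply_nocall_threshold(calls, NULL), calls)
  expect_identical(apply_nocall_threshold(calls, 1 / 3)$call, calls$call)
  t9 <- apply_nocall_threshold(calls, 0.9)
  expect_true(all(t9$call[t9$pstar < 0.9] == "NN"))
  expect_true(all(t9$call[t9$pstar >= 0.9] == calls$call[t9$pstar >= 0.9]))
  # probabilities retained; re-applying the same threshold changes nothing
  expect_identical(apply_nocall_threshold(t9, 0.9), t9)
  # monotone: raising the threshold never un-NNs a SNP
  t95 <- apply_nocall_threshold(t9, 0.95)
  expect_true(all(t95$call[t9$call == "NN"] == "NN"))
  expect_error(apply_nocall_threshold(calls, 0.2), "config error")
  expect_error(apply_nocall_threshold(calls, 1.1), "config error")
})

test_that("crosstab matches a hand-enumerated table and normalizes columns", {
  calls <- data.frame(snp_id = sprintf("s%d", 1:10),
                      call = c("AA", "AA", "AB", "AB", "BB",
                               "BB", "NN", "AA", "AB", "BB"))
  ref <- data.frame(snp_id = sprintf("s%d", c(1:8, 11, 12)),
                    call = c("AA", "AB", "AB", "AB", "BB",
                             "NN", "NN", "AA", "AA", "BB"))
  ct <- crosstab(calls, ref)
  expected <- matrix(0L, 4, 4, dimnames = list(c("AA", "AB", "BB", "NN"),
                                               c("AA", "AB", "BB", "NN")))
  expected["AA", "AA"] <- 2L  # s1, s8
  expected["AA", "AB"] <- 0L
  expected["AB", "AB"] <- 2L  # s3, s4
  expected["AB", "AA"] <- 0L
  expected["AA", "AB"] <- 1L  # s2
  expected["BB", "BB"] <- 1L  # s5
  expected["BB", "NN"] <- 1L  # s6
  expected["NN", "NN"] <- 1L  # s7
  expect_equal(ct$counts, expected, ignore_attr = TRUE)
  expect_equal(ct$n_compared, 8L)
  expect_equal(ct$n_only_calls, 2L)     # s9, s10
  expect_equal(ct$n_only_reference, 2L) # s11, s12
  nonempty <- colSums(ct$counts) > 0
  expect_equal(unname(colSums(ct$percent)[nonempty]),
               rep(100, sum(nonempty)), tolerance = 1e-9)
})

test_that("self-comparison gives a purely diagonal table", {
  fx <- .calling_fixture
  ref <- data.frame(snp_id = fx$calls$snp_id, call = fx$calls$call)
  ct <- crosstab(fx$calls, ref)
  expect_equal(sum(diag(ct$counts)), ct$n_compared)
  expect_error(crosstab(fx$calls,
                        data.frame(snp_id = "zzz", call = "AA")),
               "no overlapping")
})

test_that("crosstab totals survive label permutations of the inputs", {
  fx <- .calling_fixture
  ref <- data.frame(snp_id = fx$r$sim$truth$snp_id,
                    call = fx$r$sim$truth$genotype)
  ct <- crosstab(fx$calls, ref)
  perm <- c(AA = "BB", AB = "AA", BB = "AB", NN = "NN")
  calls2 <- fx$calls
  calls2$call <- unname(perm[calls2$call])
  ref2 <- ref
  ref2$call <- unname(perm[ref2$call])
  ct2 <- crosstab(calls2, ref2)
  expect_equal(sum(ct2$counts), sum(ct$counts))
  expect_equal(ct2$counts["BB", "BB"], ct$counts["AA", "AA"])
})

test_that("channel swap end-to-end swaps AA and BB against a swapped reference", {
  r <- small_separated_run(n = 3000, seed = 33)
  swapped <- data.frame(snp_id = r$sim$signals$snp_id,
                        signal_A = r$sim$signals$signal_B,
                        signal_B = r$sim$signals$signal_A)
  cfg <- call_config(nx = 50, ny = 50, nseg = 8)
  run1 <- genotype_array(r$sim$signals, cfg)
  run2 <- genotype_array(swapped, cfg)
  ref <- data.frame(snp_id = r$sim$truth$snp_id,
                    call = r$sim$truth$genotype)
  swap <- c(AA = "BB", AB = "AB", BB = "AA", NN = "NN")
  ref_swapped <- transform(ref, call = unname(swap[call]))
  ct1 <- crosstab(run1$calls, ref)
  ct2 <- crosstab(run2$calls, ref_swapped)
  expect_equal(ct2$counts["BB", "BB"], ct1$counts["AA", "AA"])
  expect_equal(ct2$counts["AA", "AA"], ct1$counts["BB", "BB"])
  expect_equal(ct2$counts["AB", "AB"], ct1$counts["AB", "AB"])
})

test_that("MAF follows the allele-counting definition", {
  mk <- function(calls) data.frame(snp_id = "rs1", call = calls,
                                   pstar = 1)
  tables <- lapply(c(rep("AA", 50), rep("AB", 40), rep("BB", 10)), mk)
  maf <- compute_maf(tables)
  expect_equal(maf$freq_B, (2 * 10 + 40) / 200)
  expect_equal(maf$maf, 0.3)
  maf0 <- compute_maf(lapply(rep("AA", 20), mk))
  expect_equal(maf0$maf, 0)
  # NN excluded; SNP with only NN is NA
  tnn <- list(data.frame(snp_id = c("rs1", "rs2"), call = c("AA", "NN"),
                         pstar = 1),
              data.frame(snp_id = c("rs1", "rs2"), call = c("AB", "NN"),
                         pstar = 1))
  m <- compute_maf(tnn)
  expect_equal(m$n_called[m$snp_id == "rs2"], 0L)
  expect_true(is.na(m$maf[m$snp_id == "rs2"]))
  expect_equal(m$freq_B[m$snp_id == "rs1"], 1 / 4)
})

test_that("MAF matches a direct per-allele tally on random call sets", {
  set.seed(55)
  n_arr <- 12; n_snp <- 60
  ids <- sprintf("rs%03d", 1:n_snp)
  tables <- lapply(1:n_arr, function(a)
    data.frame(snp_id = ids,
               call = sample(c("AA", "AB", "BB", "NN"), n_snp, TRUE,
                             prob = c(0.4, 0.3, 0.2, 0.1)),
               pstar = 1))
  maf <- compute_maf(tables)
  for (s in sample(ids, 10)) {
    calls <- unlist(lapply(tables, function(t) t$call[t$snp_id == s]))
    calls <- calls[calls != "NN"]
    b <- sum(calls == "BB") * 2 + sum(calls == "AB")
    f <- b / (2 * length(calls))
    expect_equal(maf$freq_B[maf$snp_id == s], f)
    expect_equal(maf$maf[maf$snp_id == s], min(f, 1 - f))
  }
})

test_that("quality summaries report pstar distributions and genotype presence", {
  fx <- .calling_fixture
  qs <- quality_summaries(fx$calls)
  expect_equal(qs$per_array$n, nrow(fx$calls))
  expect_gt(qs$per_array$median_pstar, 0.99)   # high-separation preset
  expect_equal(qs$pstar_ecdf(1), 1)
  expect_gte(min(environment(qs$pstar_ecdf)$x), 1 / 3)
  # a SNP called AA on every array has presence count 1
  t2 <- list(data.frame(snp_id = c("a", "b"), call = c("AA", "AB"),
                        pstar = c(0.9, 0.8)),
             data.frame(snp_id = c("a", "b"), call = c("AA", "BB"),
                        pstar = c(1, 0.7)))
  qs2 <- quality_summaries(t2)
  expect_equal(qs2$per_snp$n_genotypes[qs2$per_snp$snp_id == "a"], 1L)
  expect_equal(qs2$per_snp$n_genotypes[qs2$per_snp$snp_id == "b"], 2L)
  expect_equal(qs2$per_snp$mean_pstar[qs2$per_snp$snp_id == "a"], 0.95)
})
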
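test_that("a trio validates with the parents as founders", {
  ped <- trioPed()
  expect_s4_class(ped, "Pedigree")
  expect_setequal(founders(ped), c("dad", "mum"))
  expect_equal(length(pedIds(ped)), 3L)
})

test_that("structural problems are rejected with informative errors", {
  expect_error(
    Pedigree("f", "x", father = "x", mother = "x", sex = "1"),
    "cycle")
  # two-individual parent cycle
  expect_error(
    Pedigree(rep("f", 4), c("a", "b", "c", "d"),
             father = c("c", NA, "a", NA), mother = c("d", NA, "d", NA),
             sex = c("1", "2", "1", "2")),
    "cycle")
  expect_error(
    Pedigree(rep("f", 3), c("a", "b", "c"), c(NA, NA, "ghost"),
             c(NA, NA, "b"), c("1", "2", "1")),
    "dangling father")
  # female listed as father
  expect_error(
    Pedigree(rep("f", 3), c("a", "b", "c"), c(NA, NA, "b"), c(NA, NA, "a"),
             sex = c("2", "2", "1")),
    "sex inconsistency")
  expect_error(Pedigree(character(0), character(0), character(0),
                        character(0), character(0)), "no individuals")
  expect_error(
    Pedigree(rep("f", 2), c("a", "a"), c(NA, NA), c(NA, NA), c("1", "1")),
    "duplicated")
})

test_that("individuals are reordered so parents precede offspring", {
  # 12-member three-generation family listed children-first
  df <- pedData(simPedigrees(1, 12, seed = 99))
  shuffle <- rev(seq_len(nrow(df)))
  ped <- Pedigree(df$famid[shuffle], df$id[shuffle], df$father[shuffle],
                  df$mother[shuffle], df$sex[shuffle])
  out <- pedData(ped)
  pos <- seq_len(nrow(out))
  fpos <- match(out$father, out$id)
  mpos <- match(out$mother, out$id)
  expect_true(all(fpos < pos, na.rm = TRUE))
  expect_true(all(mpos < pos, na.rm = TRUE))
  expect_setequal(out$id, df$id)
})

test_that("half-specified parents get a synthesized anonymous founder", {
  expect_warning(
    ped <- Pedigree(rep("f", 3), c("a", "b", "c"), c(NA, NA, "0"),
                    c(NA, NA, "b"), c("1", "2", "1")),
    "anonymous founder")
  expect_equal(length(pedIds(ped)), 4L)
  kid <- pedData(ped)[pedData(ped)$id == "c", ]
  expect_false(is.na(kid$father))
})

test_that("kinship coefficients match the classic analytic values", {
  ped <- threeGenPed()
  phi <- kinshipMatrix(ped)
  expect_equal(phi["gf", "a"], 0.25)        # parent-offspring
  expect_equal(phi["a", "b"], 0.25)         # full sibs
  expect_equal(phi["c1", "c2"], 0.25)       # full sibs, gen 3
  expect_equal(phi["gf", "c1"], 0.125)      # grandparent-grandchild
  expect_equal(phi["b", "c1"], 0.125)       # avuncular
  expect_equal(phi["gf", "gm"], 0)          # unrelated founders
  expect_equal(unname(diag(phi)), rep(0.5, 8))  # non-inbred diagonal

  # half sibs: shared father, different mothers
  hs <- Pedigree(rep("h", 5), c("f", "m1", "m2", "k1", "k2"),
                 c(NA, NA, NA, "f", "f"), c(NA, NA, NA, "m1", "m2"),
                 c("1", "2", "2", "1", "2"))
  expect_equal(kinshipMatrix(hs)["k1", "k2"], 0.125)

  # offspring of a full-sib mating: phi(i,i) = 0.5 + 0.5 * 0.25
  inb <- Pedigree(rep("i", 5), c("a", "b", "s1", "s2", "x"),
                  c(NA, NA, "a", "a", "s1"), c(NA, NA, "b", "b", "s2"),
                  c("1", "2", "1", "2", "1"))
  expect_equal(kinshipMatrix(inb)["x", "x"], 0.625)
})

test_that("kinship is invariant to input ordering", {
  df <- pedData(simPedigrees(1, 15, seed = 42))
  phi1 <- kinshipMatrix(Pedigree(df$famid, df$id, df$father, df$mother,
                                 df$sex))
  set.seed(7)
  sh <- sample(nrow(df))
  phi2 <- kinshipMatrix(Pedigree(df$famid[sh], df$id[sh], df$father[sh],
                                 df$mother[sh], df$sex[sh]))
  ids <- sort(df$id)
  expect_equal(phi1[ids, ids], phi2[ids, ids], tolerance = 1e-12)
})

test_that("2*Phi is positive semidefinite on randomized pedigrees", {
  for (s in 1:8) {
    ped <- simPedigrees(1, 10 + 2 * s, seed = 100 + s)
    ev <- eigen(2 * kinshipMatrix(ped), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("recursive kinship agrees with Monte-Carlo gene dropping", {
  set.seed(11)
  ped <- simPedigrees(1, 15, seed = 11)
  phi <- kinshipMatrix(ped)
  est <- mcKinship(ped, ndrops = 5e4)
  expect_lt(max(abs(est - phi[rownames(est), colnames(est)])), 0.015)
})
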
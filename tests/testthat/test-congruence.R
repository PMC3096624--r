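# helper: supported tree from newick with node labels as PP values
stree <- function(txt, members) {
  supported_tree(ape::read.tree(text = txt), members)
}

test_that("a perfect mirror with private genotypes flags every entity
           congruent", {
  asg <- species_assignment(list(`1` = c("a1", "a2"), `2` = c("b1", "b2"),
                                 `3` = "c1"))
  st <- stree("((gA1:1,gA2:1)1.0:1,((gB1:1,gB2:1)1.0:0.5,gC1:1.5)1.0:0.5)1.0;",
              list(gA1 = "a1", gA2 = "a2", gB1 = "b1", gB2 = "b2",
                   gC1 = "c1"))
  res <- assess_congruence(asg, st)
  expect_equal(res$congruent, c("+", "+", "+"))
})

test_that("paraphyly, low support and shared genotypes each break
           congruence", {
  ## entity a1+a2 paraphyletic: gA1 groups with gB1
  asg <- species_assignment(list(`1` = c("a1", "a2"), `2` = "b1"))
  st_para <- stree("((gA1:1,gB1:1)0.99:1,gA2:2)1.0;",
                   list(gA1 = "a1", gA2 = "a2", gB1 = "b1"))
  expect_equal(assess_congruence(asg, st_para)$congruent[1], "-")

  ## exclusive clade but support below pp_min
  st_low <- stree("((gA1:1,gA2:1)0.80:1,gB1:2)1.0;",
                  list(gA1 = "a1", gA2 = "a2", gB1 = "b1"))
  expect_equal(assess_congruence(asg, st_low)$congruent, c("-", "+"))
  expect_equal(assess_congruence(asg, st_low, pp_min = 0.75)$congruent,
               c("+", "+"))
  ## NA support (unlabelled node) also fails
  st_na <- stree("((gA1:1,gA2:1):1,gB1:2)1.0;",
                 list(gA1 = "a1", gA2 = "a2", gB1 = "b1"))
  expect_equal(assess_congruence(asg, st_na)$congruent[1], "-")

  ## a genotype shared across entities breaks exclusivity for both
  st_shared <- stree("((gS:1,gA2:1)1.0:1,gB1:2)1.0;",
                     list(gS = c("a1", "b1"), gA2 = "a2"))
  expect_equal(assess_congruence(asg, st_shared)$congruent, c("-", "-"))
})

test_that("singleton entities need no clade support on a single tip but
           still fail on foreign individuals", {
  asg <- species_assignment(list(`1` = "a1", `2` = c("b1", "b2")))
  st <- stree("((gA:1,gB1:1)0.5:1,gB2:2)1.0;",
              list(gA = "a1", gB1 = "b1", gB2 = "b2"))
  res <- assess_congruence(asg, st)
  expect_equal(res$congruent[1], "+")   # single tip, support waived
  expect_equal(res$congruent[2], "-")   # b1+b2 not exclusive here

  ## unmapped individual is reported by name
  asg2 <- species_assignment(list(`1` = c("a1", "zz")))
  expect_error(assess_congruence(asg2, st), "zz")
})

test_that("congruence flags survive ladderization", {
  asg <- species_assignment(list(`1` = c("a1", "a2"), `2` = c("b1", "b2")))
  mem <- list(gA1 = "a1", gA2 = "a2", gB1 = "b1", gB2 = "b2")
  base <- "((gA1:1,gA2:1)0.99:1,((gB1:1,gB2:1)0.99:0.5):0.5)1.0;"
  phy <- ape::read.tree(text = base)
  res0 <- assess_congruence(asg, supported_tree(phy, mem))
  lad <- assess_congruence(asg, supported_tree(ape::ladderize(phy), mem))
  expect_equal(lad$congruent, res0$congruent)
})

test_that("topotype naming handles lumping, splitting and compound
           names", {
  md <- data.frame(
    individual = c("h1", "h2", "e1", "g1", "g2", "g3", "g4", "x1", "x2"),
    population = c("locH", "locH", "locE", "locG1", "locG1", "locG2",
                   "locG2", "p9", "p9"),
    nominal_species = c("hybrida", "hybrida", "endenensis",
                        "gratianopolitana", "gratianopolitana",
                        "gratianopolitana", "gratianopolitana", NA, NA),
    topotype = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L))

  ## entity 1 lumps the complete topotype sets of two species;
  ## entities 2 and 3 split one species' two type-locality samples;
  ## entity 4 has no topotype and mixed/missing ids -> "sp 1"
  asg <- species_assignment(list(`1` = c("h1", "h2", "e1"),
                                 `2` = c("g1", "g2"),
                                 `3` = c("g3", "g4"),
                                 `4` = c("x1", "x2")))
  named <- name_species(asg, md)
  expect_equal(unname(named$name),
               c("endenensis+hybrida", "gratianopolitana",
                 "gratianopolitana", "sp 1"))
})

test_that("unambiguous-identification naming and stable sp indices", {
  md <- data.frame(
    individual = c("a1", "a2", "b1", "b2", "c1"),
    population = paste0("p", 1:5),
    nominal_species = c("alpestris", "alpestris", "alpestris",
                        "diensis", NA),
    topotype = 0L)
  asg <- species_assignment(list(`1` = c("a1", "a2"),   # unanimous
                                 `2` = c("b1", "b2"),   # mixed ids
                                 `3` = "c1"))           # missing id
  named <- name_species(asg, md)
  expect_equal(unname(named$name), c("alpestris", "sp 1", "sp 2"))
  ## re-running yields identical names (stable indices)
  expect_identical(name_species(asg, md)$name, named$name)

  ## a split (incomplete) topotype set cannot trigger rule 1; its
  ## fragments fall through to rule 2
  md2 <- md
  md2$topotype <- c(1L, 1L, 0L, 0L, 0L)
  md2$population[1:2] <- "locA"
  asg2 <- species_assignment(list(`1` = "a1", `2` = c("a2", "b2")))
  named2 <- name_species(asg2, md2)
  expect_equal(unname(named2$name), c("alpestris", "sp 1"))

  ## topotype without a nominal species errors
  md3 <- md
  md3$topotype[5] <- 1L
  expect_error(name_species(asg, md3), "c1")
})
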
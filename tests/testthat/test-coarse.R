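mk_map <- function(domain, keys, labels) {
  methods::new("ElementMap", domain = domain,
               labels = stats::setNames(labels, keys))
}

mk_freq <- function(entries, kind = "saltbridge", system = "s") {
  ax <- AbInterface:::.element_axis
  m <- matrix(0, length(ax), length(ax), dimnames = list(ax, ax))
  for (e in entries) m[e[[1]], e[[2]]] <- e[[3]]
  methods::new("ContactFrequencyTable", system = system, kind = kind,
               ratios = m)
}

mk_table <- function(frames, res_a, res_b, kind = "saltbridge",
                     frame_count = max(frames, 1L)) {
  n <- length(frames)
  tab <- data.frame(frame = as.integer(frames),
                    kind = rep_len(kind, n),
                    subtype = rep_len(NA_character_, n),
                    ia = rep_len(1L, n), ib = rep_len(2L, n),
                    atom_a = rep_len("x", n), atom_b = rep_len("y", n),
                    residue_a = rep_len(res_a, n),
                    residue_b = rep_len(res_b, n),
                    stringsAsFactors = FALSE)
  attr(tab, "frame_count") <- frame_count
  tab
}

test_that("coarse ratios are frame unions over element pairs", {
  map_a <- mk_map("a", c("A:1", "A:2"), c("AB", "AB"))
  map_b <- mk_map("b", c("B:1", "B:2"), c("G", "G"))
  ## one salt bridge present in all frames: the characteristic
  ## AB-loop-to-G-strand bridge of a CH1-CL interface
  t1 <- mk_table(1:10, "A:1", "B:1", frame_count = 10)
  f1 <- coarseGrain(t1, map_a, map_b, system = "x")
  expect_equal(f1$saltbridge@ratios["AB", "G"], 1.0)
  expect_equal(sum(f1$saltbridge@ratios), 1.0)
  expect_equal(sum(f1$hbond@ratios), 0)
  ## two residue pairs on the same element pair, disjoint 50% frames:
  ## the union covers every frame
  t2 <- rbind(mk_table(1:5, "A:1", "B:1"), mk_table(6:10, "A:2", "B:2"))
  attr(t2, "frame_count") <- 10
  f2 <- coarseGrain(t2, map_a, map_b)
  expect_equal(f2$saltbridge@ratios["AB", "G"], 1.0)
  ## empty table: all-zero matrices
  t0 <- mk_table(integer(0), character(0), character(0), frame_count = 5)
  f0 <- coarseGrain(t0, map_a, map_b, frame_count = 5)
  expect_true(all(vapply(f0, function(t) sum(t@ratios), 0) == 0))
  ## unlabeled residue is a hard error naming the residue
  t3 <- mk_table(1, "A:99", "B:1")
  expect_error(coarseGrain(t3, map_a, map_b, frame_count = 1), "A:99")
})

test_that("coarse ratio is bounded by its constituent residue pairs", {
  cx <- toy_complex()
  sim <- synthTrajectory(cx, n_frames = 40, noise_sigma = 0.05,
                         planted = standard_plants(), seed = 31)
  tab <- trajectoryContacts(sim$traj, sim$sel_a, sim$sel_b)
  nres <- max(atoms(cx$structure)$resseq)
  map_a <- assignStrands(cx$structure,
                         domainSelection("a", sprintf("A:1-%d", nres)))
  map_b <- assignStrands(cx$structure,
                         domainSelection("b", sprintf("B:1-%d", nres)))
  freq <- coarseGrain(tab, map_a, map_b)
  for (k in names(freq)) {
    rows <- tab$kind == k
    if (!any(rows)) next
    ea <- elementOf(map_a, tab$residue_a[rows])
    eb <- elementOf(map_b, tab$residue_b[rows])
    pair_ratio <- tapply(tab$frame[rows],
                         paste(tab$residue_a[rows], tab$residue_b[rows],
                               ea, eb),
                         function(f) length(unique(f)) / 40)
    el_of_pair <- vapply(strsplit(names(pair_ratio), " "), function(p)
      paste(p[3], p[4]), "")
    for (ep in unique(el_of_pair)) {
      parts <- pair_ratio[el_of_pair == ep]
      p2 <- strsplit(ep, " ")[[1]]
      got <- freq[[k]]@ratios[p2[1], p2[2]]
      expect_gte(got, max(parts) - 1e-12)
      expect_lte(got, min(1, sum(parts)) + 1e-12)
    }
  }
})

test_that("class averages report mean and SEM with zero-imputation", {
  tabs <- lapply(c(0.2, 0.4, 0.6), function(v)
    mk_freq(list(list("AB", "G", v))))
  cs <- classAverage(tabs, "CH3-CH3")
  expect_equal(cs@mean["AB", "G"], 0.4)
  expect_equal(cs@sem["AB", "G"], 0.2 / sqrt(3), tolerance = 1e-6)
  expect_equal(cs@sem["AB", "G"], 0.11547, tolerance = 1e-4)
  expect_equal(cs@n_systems, 3L)
  ## single system: SEM 0 by convention
  cs1 <- classAverage(tabs[1], "solo")
  expect_true(all(cs1@sem == 0))
  ## n identical tables reproduce the table with SEM 0
  csn <- classAverage(rep(tabs[2], 4), "same")
  expect_equal(csn@mean, tabs[[2]]@ratios)
  expect_true(all(csn@sem == 0))
  ## all-zero tables average to zero
  cs0 <- classAverage(list(mk_freq(list())), "zero")
  expect_true(all(cs0@mean == 0))
  expect_error(classAverage(list(mk_freq(list(), "hbond"),
                                 mk_freq(list(), "vdw"))), "kinds")
})

test_that("difference maps are normalized, bounded and antisymmetric", {
  s1 <- classAverage(list(mk_freq(list(list("E", "E", 0.8)))), "c1")
  s2 <- classAverage(list(mk_freq(list(list("E", "E", 0.3),
                                       list("A", "B", 0.2)))), "c2")
  dm <- differenceMap(s1, s2)
  expect_equal(dm@delta["E", "E"], (0.8 - 0.3) / 0.8)
  expect_equal(dm@normalizer, 0.8)
  expect_true(all(abs(dm@delta) <= 1))
  dm_rev <- differenceMap(s2, s1)
  expect_equal(dm_rev@delta, -dm@delta)
  ## a contact absent from one class reaches magnitude 1 iff it is the
  ## global-maximum pair
  expect_equal(dm@delta["A", "B"], -0.2 / 0.8)
  s3 <- classAverage(list(mk_freq(list(list("E", "E", 0.0)))), "c3")
  expect_equal(max(abs(differenceMap(s1, s3)@delta)), 1)
  ## identical summaries: all zeros
  expect_true(all(differenceMap(s1, s1)@delta == 0))
  ## both all-zero: normalizer undefined
  z <- classAverage(list(mk_freq(list())), "z")
  expect_error(differenceMap(z, z), "normalizer")
})

test_that("open-book scores sum duration-weighted partner counts", {
  ## one residue bridging two permanent partners scores 2.0
  t1 <- rbind(mk_table(1:10, "A:5", "B:1", frame_count = 10),
              mk_table(1:10, "A:5", "B:2", frame_count = 10))
  attr(t1, "frame_count") <- 10
  sc <- openBookCounts(t1)
  expect_equal(unname(sc["A:5"]), 2.0)
  expect_equal(unname(sc["B:1"]), 1.0)
  ## a half-time partner contributes its ratio
  t2 <- mk_table(1:5, "A:5", "B:1", frame_count = 10)
  expect_equal(unname(openBookCounts(t2, frame_count = 10)["A:5"]), 0.5)
  ## matches a brute-force recount on a generated table
  cx <- toy_complex()
  sim <- synthTrajectory(cx, n_frames = 25, noise_sigma = 0.1,
                         planted = standard_plants(), seed = 5)
  tab <- trajectoryContacts(sim$traj, sim$sel_a, sim$sel_b)
  got <- openBookCounts(tab, kind = "saltbridge")
  sb <- tab[tab$kind == "saltbridge", ]
  want <- brute_force_openbook(sb, attr(tab, "frame_count"))
  expect_equal(got[sort(names(want))], want[sort(names(want))],
               tolerance = 1e-12)
})

test_that("flareplot JSON round-trips the frequency matrix", {
  ft <- mk_freq(list(list("AB", "G", 1.0), list("E", "DE", 0.25)))
  p <- tempfile(fileext = ".json")
  exportFlareJSON(ft, p)
  j <- jsonlite::read_json(p)
  expect_length(j$edges, 2)
  w <- vapply(j$edges, function(e) e$weight, 0)
  n1 <- vapply(j$edges, function(e) e$name1, "")
  expect_true(all(grepl("^a_", n1)))
  expect_setequal(w, c(1.0, 0.25))
  back <- readFlareJSON(p, kind = "saltbridge")
  expect_equal(back@ratios, ft@ratios)
  ## empty table: an explicit empty edge list
  p0 <- tempfile(fileext = ".json")
  exportFlareJSON(mk_freq(list()), p0)
  expect_length(jsonlite::read_json(p0)$edges, 0)
})

test_that("per-element marginals sum the partner ratios", {
  s <- classAverage(list(mk_freq(list(list("E", "E", 0.5),
                                      list("E", "DE", 0.25)))), "c")
  m <- elementMarginals(s)
  expect_equal(m$total_ratio[m$domain == "a" & m$element == "E"], 0.75)
  expect_equal(m$total_ratio[m$domain == "b" & m$element == "DE"], 0.25)
})
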
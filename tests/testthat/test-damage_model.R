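test_that("cluster construction validates and sorts lesions", {
  cl <- damage_cluster(c(105, 100), strand = c(2, 1),
                       kind = c("base_damage", "strand_break"))
  expect_s3_class(cl, "damage_cluster")
  expect_equal(cl$position, c(100L, 105L))
  expect_equal(cl$kind, c("strand_break", "base_damage"))
  expect_equal(cluster_multiplicity(cl), 2L)
  expect_error(damage_cluster(integer(0)), "at least one lesion")
  expect_error(damage_cluster(0), "coordinates")
  expect_error(damage_cluster(10, strand = 3), "strand")
  expect_error(damage_cluster(10, kind = "nick"), "kind")
})

test_that("classifier reproduces the seven-category proximity rules", {
  # simple DSB: opposite strands, separation < 10 bp
  expect_equal(classify_cluster(damage_cluster(c(100, 105), strand = c(1, 2))),
               "DSB")
  # no breaks at all: base damage
  expect_equal(classify_cluster(damage_cluster(100, 1, "base_damage")), "BD")
  expect_equal(classify_cluster(damage_cluster(100, 1, "abasic_site")), "BD")
  # opposite strands but separation >= 10: two SSBs, not a DSB
  expect_equal(classify_cluster(damage_cluster(c(100, 115), strand = c(1, 2))),
               "SSB2")
  # DSB with an extra break on a strand within 10 bp
  expect_equal(classify_cluster(
    damage_cluster(c(100, 104, 107), strand = c(1, 2, 1))), "DSBp")
  # two disjoint DSBs in proximity
  expect_equal(classify_cluster(
    damage_cluster(c(100, 101, 105, 106), strand = c(1, 2, 1, 2))), "DSBpp")
  # single and multiple breaks confined to one strand
  expect_equal(classify_cluster(damage_cluster(100, 1)), "SSB")
  expect_equal(classify_cluster(damage_cluster(c(100, 104), strand = 1)),
               "SSBp")
  # boundary: separation 9 is a DSB, separation 10 is not
  expect_equal(classify_cluster(damage_cluster(c(100, 109), strand = c(1, 2))),
               "DSB")
  expect_equal(classify_cluster(damage_cluster(c(100, 110), strand = c(1, 2))),
               "SSB2")
  expect_error(classify_cluster(list(position = integer(0))), "cluster")
})

test_that("classifier agrees with the brute-force oracle on small clusters", {
  kinds <- lesion_kinds()
  # exhaustive two-lesion geometries within a 30 bp window
  for (sep in 0:29) {
    for (k1 in kinds) {
      for (k2 in kinds) {
        for (s2 in 1:2) {
          cl <- damage_cluster(c(100L, 100L + sep), strand = c(1L, s2),
                               kind = c(k1, k2))
          expect_equal(
            classify_cluster(cl),
            oracle_classify(cl$position, cl$strand, cl$kind),
            info = sprintf("sep=%d %s/%s strands 1/%d", sep, k1, k2, s2))
        }
      }
    }
  }
  # random clusters of 3-5 lesions
  withr::with_seed(421, {
    for (rep in 1:600) {
      cl <- random_cluster(sample(3:5, 1))
      got <- classify_cluster(cl)
      expect_equal(got, oracle_classify(cl$position, cl$strand, cl$kind),
                   info = paste(capture.output(as.data.frame(cl)),
                                collapse = "; "))
      # category exclusivity: exactly one of the seven labels
      expect_true(got %in% damage_categories())
    }
  })
})

test_that("spectrum totals follow the bookkeeping identities", {
  sp <- fixture_spectrum("P6")
  tot <- aggregate_totals(sp)
  expect_equal(signif(tot[["total_DSB"]], 3), 12.4)
  # 154 + 13.9 + 3.08 = 170.98; the published table prints 170 because its
  # totals were rounded from unrounded category values
  expect_equal(signif(tot[["total_SSB"]], 3), 171)
  p1 <- aggregate_totals(fixture_spectrum("P1"))
  expect_equal(signif(p1[["total_SSB"]], 3), 187)
  zero <- setNames(numeric(7), damage_categories())
  expect_equal(unname(aggregate_totals(zero)), c(0, 0, 0))
  expect_error(aggregate_totals(zero[-1]), "missing damage categories")
})

test_that("damage_spectrum enforces the multiplicity-sum invariant", {
  y <- setNames(c(10, 5, 0, 0, 2, 0, 0), damage_categories())
  ok <- damage_spectrum(y, multiplicity_yields = data.frame(
    category = c("BD", "BD", "SSB", "DSB"),
    multiplicity = c(1, 2, 1, 2),
    yield = c(9, 1, 5, 2)))
  expect_s3_class(ok, "damage_spectrum")
  expect_error(
    damage_spectrum(y, multiplicity_yields = data.frame(
      category = "BD", multiplicity = 1, yield = 9.5)),
    "do not sum")
  expect_error(damage_spectrum(y[-3]), "named over all categories")
  y_neg <- y; y_neg[1] <- -1
  expect_error(damage_spectrum(y_neg), ">= 0")
})

test_that("yield tables and cluster JSON round-trip through disk", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(position = "X1", oxygen_pct = 21,
                   BD = 400, SSB = 170, SSBp = 8, SSB2 = 1,
                   DSB = 7, DSBp = 1, DSBpp = 0.1)
  write_damage_yields(df, tmp)
  expect_equal(read_damage_yields(tmp), df)
  expect_error(read_damage_yields("no/such/file.tsv"), "not found")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("position\toxygen_pct\tBD\nX\t21\t1", bad)
  expect_error(read_damage_yields(bad), "missing column")

  cj <- withr::local_tempfile(fileext = ".json")
  clusters <- list(damage_cluster(c(100, 103), strand = c(1, 2),
                                  kind = c("strand_break", "base_damage")),
                   damage_cluster(50, 2, "abasic_site"))
  write_clusters_json(clusters, cj)
  back <- read_clusters_json(cj)
  expect_equal(back, clusters)
})
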
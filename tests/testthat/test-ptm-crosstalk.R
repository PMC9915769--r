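test_that("site-to-motif distance follows the gap convention", {
  spans <- tibble::tibble(start = 145L, end = 149L)
  # 30 residues strictly between T114 and the P145..I149 span
  expect_identical(site_motif_distance(114L, spans), 30L)
  expect_identical(site_motif_distance(147L, spans), 0L)   # inside the span
  expect_identical(site_motif_distance(150L, spans), 0L)   # adjacent
  expect_identical(site_motif_distance(150L, spans, convention = "nearest"),
                   1L)
  # minimised over multiple hits
  spans2 <- tibble::tibble(start = c(20L, 145L), end = c(24L, 149L))
  expect_identical(site_motif_distance(114L, spans2), 30L)
  expect_identical(site_motif_distance(30L, spans2), 5L)
  expect_error(site_motif_distance(10L, spans2[0, ]), "no motif hits")
})

test_that("crosstalk summary reproduces printed overlap percentages", {
  proteome <- make_overlap_fixture()
  hits <- scan_proteome(proteome, "PxYx[IL]")
  s <- summarize_crosstalk(proteome, hits, window = 100)
  expect_identical(s$n_motif_proteins, 223L)
  expect_identical(s$n_oglcnac_proteins, 126L)
  expect_identical(s$pct_oglcnac_proteins, 56.5)
  expect_identical(s$n_proteins_with_sites, 89L)
  expect_identical(s$n_sites_assigned, 374L)
  expect_identical(s$n_sites_within_window, 64L)
  expect_identical(s$pct_sites_within_window, 17.1)
  expect_identical(s$n_ptyr_proteins, 189L)
  expect_identical(s$pct_ptyr_proteins, 84.8)
  expect_identical(s$n_motif_ptyr_proteins, 61L)
  expect_identical(s$pct_motif_ptyr_proteins, 32.3)
  expect_identical(s$n_motif_ptyr_with_oglcnac, 47L)
  expect_identical(s$pct_motif_ptyr_with_oglcnac, 77.0)
})

test_that("an annotation-free universe yields zero fractions and no histogram", {
  proteome <- make_proteome(
    make_protein("P1", "AAPVYQIAA"),
    make_protein("P2", "AAPVYQLAA"))
  hits <- scan_proteome(proteome, "PxYx[IL]")
  s <- summarize_crosstalk(proteome, hits)
  expect_identical(s$n_motif_proteins, 2L)
  expect_identical(s$n_sites_assigned, 0L)
  expect_identical(s$pct_sites_within_window, 0)
  expect_identical(s$pct_ptyr_proteins, 0)
  expect_identical(nrow(distance_histogram(s)), 0L)
})

test_that("the distance histogram bins at fixed residue edges", {
  proteome <- make_proteome(
    make_protein("P1", paste0("AA", "PAYAI", strrep("A", 200)),
                 oglcnac_sites = c(10L, 30L, 130L)))
  hits <- scan_proteome(proteome, "PxYx[IL]")
  s <- summarize_crosstalk(proteome, hits)
  h <- distance_histogram(s, bin_width = 10)
  # distances: 10-7+... site 10 vs span 3..7 -> 2; site 30 -> 22; 130 -> 122
  expect_identical(s$sites$distance, c(2L, 22L, 122L))
  expect_identical(h$bin_start[h$n_all > 0], c(0L, 20L, 120L))
  expect_identical(sum(h$n_all), 3L)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  # forced draw: every universe member drawn -> p = 1
  r1 <- enrich_sets(letters[1:4], list(t1 = letters[1:4]), letters[1:4])
  expect_identical(r1$p, 1)

  # N=10, K=5, n=4, k=4 -> C(5,4)/C(10,4) = 5/210
  universe <- sprintf("u%02d", 1:10)
  q <- universe[1:4]
  r2 <- enrich_sets(q, list(t1 = universe[1:5]), universe)
  expect_equal(r2$p, 5 / 210, tolerance = 1e-12)

  # k=0 -> p=1
  r3 <- enrich_sets(universe[6:9], list(t1 = universe[1:5]), universe)
  expect_identical(r3$p, 1)

  expect_warning(enrich_sets(q, list(bad = "zzz"), universe), "no members")
  expect_error(enrich_sets("zzz", list(t1 = universe), universe), "subset")
})

test_that("enrichment p-values match the enumeration oracle on small universes", {
  set.seed(606)
  for (i in 1:15) {
    N <- sample(6:12, 1)
    universe <- sprintf("p%02d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    query <- sample(universe, n)
    r <- enrich_sets(query, list(t = universe[seq_len(K)]), universe)
    k <- length(intersect(query, universe[seq_len(K)]))
    expect_equal(r$p, hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("BH correction preserves p-value order and flags q < 0.05", {
  universe <- sprintf("g%03d", 1:60)
  query <- universe[1:12]
  terms <- list(strong = universe[1:12],          # perfectly enriched
                weak = universe[c(1:3, 30:44)],
                null = universe[40:49])
  r <- enrich_sets(query, terms, universe)
  expect_false(is.unsorted(r$q))
  expect_true(r$significant[r$term == "strong"])
  expect_identical(r$significant, r$q < 0.05)
})

test_that("a planted proximal-enrichment in the motif-pTyr subset is recovered", {
  spec <- synth_proteome_spec(
    n_proteins = 120, motif_carrier_fraction = 1,
    oglcnac_near_motif_fraction = 0.171,
    oglcnac_near_motif_fraction_motif_ptyr = 0.33,
    ptyr_on_motif_fraction = 0.5, oglcnac_sites_per_protein = 4, seed = 77)
  proteome <- generate_proteome(spec)
  hits <- scan_proteome(proteome, spec$planted_motif)
  s <- summarize_crosstalk(proteome, hits)
  expect_gt(s$pct_motif_ptyr_sites_within, s$pct_sites_within_window)
})
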
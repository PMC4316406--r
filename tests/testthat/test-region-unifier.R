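test_that("unify forms covering spans by transitive overlap chaining", {
  expect_equal(nrow(unify(peak_df("c1", numeric(0), numeric(0)),
                          peak_df("c1", numeric(0), numeric(0)))), 0)

  e <- peak_df("c1", c(100, 300), c(200, 400), read_count = c(5, 6))
  n <- peak_df("c1", 150, 350, read_count = 7)
  reg <- unify(e, n)
  expect_equal(nrow(reg), 1)
  expect_equal(c(reg$start, reg$end), c(100, 400))
  expect_equal(reg$origin, "both")
  expect_equal(reg$k_embryo, 11)
  expect_equal(reg$k_endosperm, 7)

  # a tissue-exclusive peak is its own region
  reg <- unify(peak_df("c1", 500, 600, read_count = 9),
               peak_df("c1", numeric(0), numeric(0)))
  expect_equal(c(reg$start, reg$end), c(500, 600))
  expect_equal(reg$origin, "embryo_only")
  expect_equal(reg$k_endosperm, 0)
})

test_that("book-ended peaks do not merge and unknown chroms are fatal", {
  reg <- unify(peak_df("c1", 0, 100), peak_df("c1", 100, 200))
  expect_equal(nrow(reg), 2)
  expect_error(unify(peak_df("cX", 0, 100),
                     peak_df("c1", 0, 100), chroms = "c1"), "cX")
})

test_that("unify agrees with a graph connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (rep in 1:25) {
    ne <- sample(0:20, 1); nn <- sample(0:20, 1)
    mk <- function(n) {
      if (n == 0) return(peak_df("c1", numeric(0), numeric(0)))
      s <- sample(0:2000, n)
      peak_df(sample(c("c1", "c2"), n, replace = TRUE), s,
              s + sample(20:400, n, replace = TRUE),
              read_count = sample(1:50, n, replace = TRUE))
    }
    e <- mk(ne); n <- mk(nn)
    reg <- unify(e, n)
    pool <- rbind(e[, 1:3], n[, 1:3])
    if (nrow(pool) == 0) { expect_equal(nrow(reg), 0); next }
    # oracle: explicit overlap graph, components, covering spans
    adj <- outer(seq_len(nrow(pool)), seq_len(nrow(pool)),
                 Vectorize(function(i, j)
                   pool$chrom[i] == pool$chrom[j] &&
                   pool$start[i] < pool$end[j] &&
                   pool$start[j] < pool$end[i]))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    spans <- do.call(rbind, lapply(split(seq_along(comp), comp),
      function(ix) data.frame(chrom = pool$chrom[ix[1]],
                              start = min(pool$start[ix]),
                              end = max(pool$end[ix]))))
    spans <- spans[order(spans$chrom, spans$start), ]
    expect_equal(reg$chrom, spans$chrom)
    expect_equal(reg$start, spans$start)
    expect_equal(reg$end, spans$end)
    # peak conservation and non-overlap of regions
    expect_equal(sum(reg$n_peaks_embryo) + sum(reg$n_peaks_endosperm),
                 nrow(pool))
    for (ch in unique(reg$chrom)) {
      rc <- reg[reg$chrom == ch, ]
      expect_true(all(rc$start[-1] >= rc$end[-nrow(rc)]))
    }
  }
})

test_that("unify is idempotent and symmetric in tissue labels", {
  set.seed(12)
  s <- sample(0:3000, 30)
  e <- peak_df("c1", s[1:15], s[1:15] + 150, read_count = 1:15)
  n <- peak_df("c1", s[16:30], s[16:30] + 150, read_count = 16:30)
  reg <- unify(e, n)
  reg2 <- unify(peak_df(reg$chrom, reg$start, reg$end,
                        read_count = reg$k_embryo),
                peak_df("c1", numeric(0), numeric(0)))
  expect_equal(reg2[, c("chrom", "start", "end")],
               reg[, c("chrom", "start", "end")])
  swapped <- unify(n, e)
  expect_equal(swapped[, c("chrom", "start", "end")],
               reg[, c("chrom", "start", "end")])
  expect_equal(swapped$k_embryo, reg$k_endosperm)
  expect_equal(swapped$origin,
               c(both = "both", embryo_only = "endosperm_only",
                 endosperm_only = "embryo_only")[reg$origin],
               ignore_attr = TRUE)
})

test_that("reads are assigned to regions by midpoint, exactly once", {
  reg <- unify(peak_df("c1", c(100, 400), c(400, 700)),
               peak_df("c1", numeric(0), numeric(0)))
  expect_equal(nrow(reg), 2)  # book-ended: stay separate
  # read [95,145) has midpoint 120 -> first region
  upd <- count_reads_in_regions(reg, iv("c1", 95, 145), "embryo")
  expect_equal(upd$k_embryo, c(1, 0))
  # a read bridging both regions is counted once, by midpoint
  upd <- count_reads_in_regions(reg, iv("c1", 380, 420), "embryo")
  expect_equal(sum(upd$k_embryo), 1)
  expect_equal(upd$k_embryo, c(0, 1))  # midpoint 400 lies in [400,700)
  # conservation: uniform reads over a fully tiled chromosome
  set.seed(13)
  one <- unify(peak_df("c1", 0, 10000), peak_df("c1", numeric(0), numeric(0)))
  starts <- sample(0:9900, 1000, replace = TRUE)
  upd <- count_reads_in_regions(one, iv("c1", starts, starts + 50),
                                "endosperm")
  expect_equal(upd$k_endosperm, 1000)
})
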
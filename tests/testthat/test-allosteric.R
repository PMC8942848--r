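test_that("binned MI matches the closed form on a printed joint table", {
  cts <- mi_oracle_table()
  s <- series_from_counts(cts)
  bx <- gpcrdimer:::bin_angles(s$x, 3)
  by <- gpcrdimer:::bin_angles(s$y, 3)
  expect_equal(gpcrdimer:::mi_binned(bx, by, 3), mi_from_counts(cts),
               tolerance = 1e-9)
  ## MI(X, X) equals the binned entropy
  expect_equal(gpcrdimer:::mi_binned(bx, bx, 3),
               gpcrdimer:::entropy_binned(bx, 3), tolerance = 1e-12)
  ## identical uniform 12-level series: MI ~ log2(12)
  x <- rep(seq(-165, 165, by = 30), length.out = 1200)
  b12 <- gpcrdimer:::bin_angles(x, 12)
  expect_equal(gpcrdimer:::mi_binned(b12, b12, 12), log2(12),
               tolerance = 1e-9)
})

test_that("independent series give corrected MI <= 0.05 bits (null calibration)", {
  sp <- synthetic_spec(n_res = 5, n_frames = 2000, chain_residues = NULL,
                       seed = 7)
  sim <- simulate_coupled_torsion_trajectory(sp)
  net <- torsion_mutual_information(compute_torsions(sim$trajectory),
                                    bins = 24, n_perm = 20, seed = 11)
  v <- net$mi[upper.tri(net$mi)]
  expect_gte(mean(v <= 0.05), 0.95)
  ## symmetry and non-negativity
  expect_true(all(net$mi >= 0))
  expect_equal(net$mi, t(net$mi))
  expect_true(all(diag(net$mi) == 0))
})

test_that("coupled pairs carry high MI, bounded by the 1-bit hidden mode", {
  chain <- data.frame(chain = "R", resno = 3:6)
  sp <- synthetic_spec(n_res = 8, n_frames = 2000, chain_residues = chain,
                       kappa = 8, mode_offset_deg = 120, seed = 13)
  sim <- simulate_coupled_torsion_trajectory(sp)
  net <- torsion_mutual_information(compute_torsions(sim$trajectory),
                                    bins = 24, n_perm = 20, seed = 13)
  i <- which(net$residues$chain == "R" & net$residues$resno == 3)
  j <- which(net$residues$chain == "R" & net$residues$resno == 4)
  ## raw binned MI exceeds 1 bit (finite-sample bias); the corrected
  ## estimate approaches the 1-bit information bound from below
  expect_gte(net$raw[i, j], 1.0)
  expect_gte(net$mi[i, j], 0.85)
  expect_lte(net$mi[i, j], 1.05)
  ## null pair stays at noise level
  k <- which(net$residues$chain == "S" & net$residues$resno == 1)
  expect_lte(net$mi[i, k], 0.05)
})

test_that("graph eligibility and weights behave as designed", {
  ## 3 residues in a row: eligibility prunes the long-range pair
  chain <- data.frame(chain = "R", resno = 1:12)
  sp <- synthetic_spec(n_res = 12, n_frames = 150, chain_residues = chain,
                       seed = 17)
  sim <- suppressWarnings(simulate_coupled_torsion_trajectory(sp))
  net <- torsion_mutual_information(compute_torsions(sim$trajectory),
                                    bins = 24, n_perm = 5, seed = 17)
  topo <- make_toy_dimer_states(synthetic_spec(n_res = 12))$state_a
  g <- build_mi_graph(net, topo, cutoff = 7)
  keyof <- function(r) sprintf("R|%d|", r)
  has_edge <- function(g, a, b) {
    ia <- match(a, g$nodes); ib <- match(b, g$nodes)
    any((g$edges$from == ia & g$edges$to == ib) |
        (g$edges$from == ib & g$edges$to == ia))
  }
  expect_true(has_edge(g, keyof(1), keyof(2)))      # 3.8 A apart
  expect_false(has_edge(g, keyof(1), keyof(12)))    # 16.5 A apart
  ## weight is a monotone decreasing transform of MI
  ord <- order(g$edges$mi)
  expect_true(all(diff(g$edges$weight[ord]) <= 1e-12))
  ## equal MI -> equal weight on eligible edges
  net0 <- net; net0$mi[] <- 0.5; diag(net0$mi) <- 0
  g0 <- build_mi_graph(net0, topo, cutoff = 7)
  expect_equal(stats::sd(g0$edges$weight), 0)
})

test_that("Dijkstra equals exhaustive enumeration on small random graphs", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    ## random connected-ish graph with positive weights
    edges <- NULL
    for (i in 1:(n - 1)) edges <- rbind(edges, c(i, i + 1))  # path backbone
    extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    extra <- extra[sample(nrow(extra), min(n, nrow(extra))), , drop = FALSE]
    edges <- unique(rbind(edges, extra))
    w <- stats::runif(nrow(edges), 0.1, 2)
    mi <- stats::runif(nrow(edges), 0, 1)
    g <- structure(list(
      nodes = sprintf("R|%d|", 1:n),
      edges = data.frame(from = edges[, 1], to = edges[, 2], mi = mi,
                         weight = w),
      adj = local({
        adj <- vector("list", n)
        for (r in seq_len(nrow(edges))) {
          i <- edges[r, 1]; j <- edges[r, 2]
          adj[[i]] <- rbind(adj[[i]], c(j, w[r], mi[r]))
          adj[[j]] <- rbind(adj[[j]], c(i, w[r], mi[r]))
        }
        adj
      }),
      mi = local({
        M <- matrix(0, n, n)
        for (r in seq_len(nrow(edges)))
          M[edges[r, 1], edges[r, 2]] <- M[edges[r, 2], edges[r, 1]] <- mi[r]
        M
      })), class = "mi_graph")
    src <- 1; dst <- n
    dj <- gpcrdimer:::dijkstra_path(g, src, dst)
    oracle <- enumerate_min_path(g, src, dst)
    expect_equal(dj$weight, oracle$weight, tolerance = 1e-9)
  }
})

test_that("site residues obey the strict >60% frequency rule with a recount", {
  sp <- synthetic_spec(n_frames = 10, seed = 19, contacts = data.frame(
    res_a = 1:5, res_b = 1:5, frequency = c(1.0, 0.7, 0.6, 0.3, 0.0)))
  pc <- plant_contact_series(sp)
  sr <- define_site_residues(pc$trajectory, "S", 0.60,
                             receptor_chains = "R")
  expect_setequal(sr$resno, c(1, 2))          # 0.6 excluded (strict)
  ## brute-force per-frame recount oracle
  recount <- sapply(1:5, function(r) {
    hits <- 0
    for (f in 1:10) {
      m <- frame_model(pc$trajectory, f)
      res <- ligand_contact_residues(m, "S", "R")
      if (r %in% res$resno) hits <- hits + 1
    }
    hits / 10
  })
  expect_equal(unname(recount[sr$resno]), sr$frequency, tolerance = 1e-12)
  expect_error(define_site_residues(pc$trajectory, "Z"),
               class = "format_error")
})

test_that("pipelines are optimal, ranked by strength, and hubscores tally", {
  ## deterministic 6-node fixture with two competing routes
  n <- 6
  edges <- data.frame(from = c(1, 2, 3, 1, 5, 4),
                      to = c(2, 3, 4, 5, 6, 6),
                      mi = c(0.9, 0.9, 0.9, 0.2, 0.2, 0.9))
  edges$weight <- -log(edges$mi / max(edges$mi) + 1e-6)
  adj <- vector("list", n)
  M <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$from[r]; j <- edges$to[r]
    adj[[i]] <- rbind(adj[[i]], c(j, edges$weight[r], edges$mi[r]))
    adj[[j]] <- rbind(adj[[j]], c(i, edges$weight[r], edges$mi[r]))
    M[i, j] <- M[j, i] <- edges$mi[r]
  }
  g <- structure(list(nodes = sprintf("R|%d|", 1:n), edges = edges,
                      adj = adj, mi = M), class = "mi_graph")
  pipes <- shortest_pipelines(g, "R|1|", "R|6|", top_n = 5)
  expect_length(pipes, 1L)
  expect_equal(pipes[[1]]$path, sprintf("R|%d|", c(1, 2, 3, 4, 6)))
  oracle <- enumerate_min_path(g, 1, 6)
  expect_equal(pipes[[1]]$weight, oracle$weight, tolerance = 1e-12)
  expect_equal(pipes[[1]]$strength, 4 * 0.9, tolerance = 1e-12)
  ## star topology: all pipelines pass through the hub
  star_edges <- data.frame(from = rep(1, 5), to = 2:6, mi = 0.5)
  star_edges$weight <- 1
  sadj <- vector("list", 6); SM <- matrix(0, 6, 6)
  for (r in seq_len(nrow(star_edges))) {
    i <- star_edges$from[r]; j <- star_edges$to[r]
    sadj[[i]] <- rbind(sadj[[i]], c(j, 1, 0.5))
    sadj[[j]] <- rbind(sadj[[j]], c(i, 1, 0.5))
    SM[i, j] <- SM[j, i] <- 0.5
  }
  gs <- structure(list(nodes = sprintf("R|%d|", 1:6), edges = star_edges,
                       adj = sadj, mi = SM), class = "mi_graph")
  pipes_s <- shortest_pipelines(gs, sprintf("R|%d|", 2:3),
                                sprintf("R|%d|", 5:6), top_n = 10)
  expect_length(pipes_s, 4L)
  hs <- hubscores(pipes_s)
  expect_equal(hs$hubscore[hs$residue == "R|1|"], 4L)  # hub on every path
  ## recount oracle
  tally <- table(unlist(lapply(pipes_s, `[[`, "path")))
  for (k in seq_len(nrow(hs)))
    expect_equal(hs$hubscore[k], unname(as.integer(tally[hs$residue[k]])))
  ## disjoint pipelines -> all hubscores 1
  pipes_d <- list(list(path = c("A|1|", "A|2|")), list(path = c("B|1|", "B|2|")))
  class(pipes_d) <- "pipeline_list"
  expect_true(all(hubscores(pipes_d)$hubscore == 1L))
})

test_that("a planted chain is recovered through the full pipeline", {
  n <- 20
  chain <- data.frame(chain = c(rep("R", 4), rep("S", 4)),
                      resno = c(15:18, 15:18))
  sp <- synthetic_spec(n_res = n, n_frames = 400, chain_residues = chain,
                       kappa = 8, mode_offset_deg = 120, seed = 5)
  sim <- simulate_coupled_torsion_trajectory(sp)
  net <- torsion_mutual_information(compute_torsions(sim$trajectory),
                                    bins = 24, n_perm = 10, seed = 5)
  topo <- make_toy_dimer_states(synthetic_spec(n_res = n),
                                separation = 8)$state_a
  g <- build_mi_graph(net, topo, cutoff = 10)
  pipes <- shortest_pipelines(g, "R|15|", "S|18|", top_n = 10)
  expect_gte(length(pipes), 1L)
  planted_keys <- sprintf("%s|%d|", chain$chain, chain$resno)
  ## the top pipeline crosses the interface and stays on the planted chain
  expect_true(all(pipes[[1]]$path %in% planted_keys))
  expect_true(any(grepl("^R", pipes[[1]]$path)) &&
              any(grepl("^S", pipes[[1]]$path)))
  hs <- hubscores(pipes)
  expect_true(all(hs$residue %in% planted_keys))
})

test_that("source/target validation and unreachable pairs are handled", {
  edges <- data.frame(from = 1, to = 2, mi = 0.5, weight = 1)
  adj <- list(rbind(c(2, 1, 0.5)), rbind(c(1, 1, 0.5)), NULL)
  M <- matrix(0, 3, 3); M[1, 2] <- M[2, 1] <- 0.5
  g <- structure(list(nodes = c("R|1|", "R|2|", "R|3|"), edges = edges,
                      adj = adj, mi = M), class = "mi_graph")
  pipes <- shortest_pipelines(g, "R|1|", c("R|2|", "R|3|"), top_n = 5)
  expect_length(pipes, 1L)                       # R|3| unreachable
  expect_equal(attr(pipes, "n_unreachable"), 1L)
  expect_error(shortest_pipelines(g, "R|9|", "R|2|"),
               class = "configuration_error")
  expect_error(hubscores(structure(list(), class = "pipeline_list")),
               class = "configuration_error")
})
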
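#' Torsion mutual-information allosteric network analysis
#'
#' Residue-residue mutual information (MI) in torsion-angle distributions,
#' an MI-weighted residue graph restricted to spatially proximal pairs,
#' highest-MI shortest "pipelines" between a ligand-binding site and a
#' G-protein-coupling site, pipeline ranking by strength, and per-residue
#' hubscores (the number of retained pipelines passing through a residue).
#'
#' @name allosteric
NULL

## bin angles (-180,180] into 1..bins equal circular bins
bin_angles <- function(x, bins) {
  b <- floor((x + 180) / (360 / bins)) + 1L
  b[b > bins] <- bins  # x == 180 lands in the last bin
  as.integer(b)
}

## MI (bits) between two integer bin series of equal length
mi_binned <- function(bx, by, bins) {
  n <- length(bx)
  joint <- tabulate(bx + bins * (by - 1L), nbins = bins * bins) / n
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  nz <- joint > 0
  denom <- outer(px, py)[nz]
  sum(joint[nz] * log2(joint[nz] / denom))
}

## binned entropy in bits
entropy_binned <- function(bx, bins) {
  p <- tabulate(bx, nbins = bins) / length(bx)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Residue-pair torsion mutual information network
#'
#' For every residue pair, MI is computed between each pair of available
#' torsions (phi/psi/chi1, up to 9 combinations) on equal-width circular
#' bins; the residue-pair MI is the maximum over torsion pairs (the
#' strongest coupling channel). Finite-sample bias is estimated per torsion
#' pair as the mean MI over `n_perm` seeded permutation shuffles of one
#' series and subtracted, floored at zero.
#'
#' @param series a `TorsionSeries` from [compute_torsions()]
#' @param bins number of circular bins (default 24, i.e. 15 degrees)
#' @param n_perm permutation shuffles for bias correction (0 disables)
#' @param seed RNG seed for the permutations
#' @return an `MINetwork`: list with `residues`, `mi` (corrected, residue
#'   pair matrix, bits), `raw` (uncorrected), `bins`, `n_perm`, `seed`
#' @export
torsion_mutual_information <- function(series, bins = 24, n_perm = 20,
                                       seed = 1) {
  if (bins < 6) abort("need at least 6 bins", "configuration_error")
  ang <- series$angles
  nf <- dim(ang)[1]
  if (nf < 100)
    warning(sprintf("only %d frames; MI estimates will be noisy (>=100 recommended)",
                    nf))
  nr <- dim(ang)[2]
  ## per-residue list of binned torsion series (drop masked/constant-NA)
  binned <- vector("list", nr)
  for (i in seq_len(nr)) {
    cols <- list()
    for (t in 1:3) {
      v <- ang[, i, t]
      if (!anyNA(v)) cols[[length(cols) + 1L]] <- bin_angles(v, bins)
    }
    binned[[i]] <- cols
  }
  keep <- vapply(binned, length, 1L) > 0
  if (any(!keep))
    warning(sprintf("%d residue(s) dropped: all torsions masked", sum(!keep)))
  res <- series$residues[keep, , drop = FALSE]
  binned <- binned[keep]
  nr <- length(binned)
  ## shared permutation index matrix (seeded): reused across pairs
  perms <- NULL
  if (n_perm > 0) {
    rs <- local({ set.seed(seed)
      replicate(n_perm, sample.int(nf), simplify = FALSE) })
    perms <- rs
  }
  mi <- matrix(0, nr, nr)
  raw <- matrix(0, nr, nr)
  for (i in seq_len(nr - 1L)) {
    for (j in seq((i + 1L), nr)) {
      best_c <- 0; best_r <- 0
      for (bx in binned[[i]]) for (by in binned[[j]]) {
        r <- mi_binned(bx, by, bins)
        bias <- 0
        if (n_perm > 0) {
          bias <- mean(vapply(perms, function(p) mi_binned(bx[p], by, bins),
                              numeric(1)))
        }
        cval <- max(0, r - bias)
        if (cval > best_c) best_c <- cval
        if (r > best_r) best_r <- r
      }
      mi[i, j] <- mi[j, i] <- best_c
      raw[i, j] <- raw[j, i] <- best_r
    }
  }
  keys <- res_key(res$chain, res$resno, res$icode)
  dimnames(mi) <- dimnames(raw) <- list(keys, keys)
  structure(list(residues = res, mi = mi, raw = raw, bins = bins,
                 n_perm = n_perm, seed = seed),
            class = "MINetwork")
}

#' Build the MI-weighted residue graph
#'
#' Edges connect residue pairs whose mean C-alpha to C-alpha distance is
#' at most `cutoff` (spatial contiguity: pipelines are chains of
#' physically interacting residues and may cross the dimer interface).
#' Edge weight is `-log(MI_ij / MI_max + eps)` so that minimum-weight
#' paths are highest-MI paths.
#'
#' @param network an `MINetwork`
#' @param topology a [StructureModel] (static distances) or a
#'   [Trajectory] (mean over frames)
#' @param cutoff C-alpha distance cutoff, Angstrom
#' @param eps weight-regularisation constant
#' @return an `mi_graph`: list with `nodes` (residue keys), `edges`
#'   (data frame from, to, mi, weight), `adj` (adjacency index list)
#' @export
build_mi_graph <- function(network, topology, cutoff = 10, eps = 1e-6) {
  keys <- res_key(network$residues$chain, network$residues$resno,
                  network$residues$icode)
  ## mean CA position per residue
  ca_pos <- function(model) {
    at <- model$atoms
    sel <- at$atom == "CA" & !at$het
    k <- atom_res_key(at)[sel]
    X <- as.matrix(at[sel, c("x", "y", "z")])
    X[match(keys, k), , drop = FALSE]
  }
  if (inherits(topology, "Trajectory")) {
    acc <- matrix(0, length(keys), 3)
    for (f in seq_len(n_frames(topology)))
      acc <- acc + ca_pos(frame_model(topology, f))
    X <- acc / n_frames(topology)
  } else X <- ca_pos(topology)
  if (anyNA(X))
    abort("missing C-alpha for some network residues in topology",
          "topology_error")
  D <- as.matrix(stats::dist(X))
  mimax <- max(network$mi)
  if (mimax <= 0) mimax <- 1
  n <- length(keys)
  el <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)
  w <- -log(network$mi[el] / mimax + eps)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      mi = network$mi[el], weight = w)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$from[r]; j <- edges$to[r]
    adj[[i]] <- rbind(adj[[i]], c(j, edges$weight[r], edges$mi[r]))
    adj[[j]] <- rbind(adj[[j]], c(i, edges$weight[r], edges$mi[r]))
  }
  structure(list(nodes = keys, edges = edges, adj = adj, cutoff = cutoff,
                 eps = eps, mi = network$mi),
            class = "mi_graph")
}

## Dijkstra with deterministic tie-breaks: on equal distance prefer fewer
## hops, then smaller predecessor index. O(V^2), fine at residue scale.
dijkstra_path <- function(graph, src, dst) {
  n <- length(graph$nodes)
  dist <- rep(Inf, n); hops <- rep(Inf, n); prev <- rep(NA_integer_, n)
  dist[src] <- 0; hops[src] <- 0
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[order(dist[cand], hops[cand], cand)][1]
    if (u == dst) break
    done[u] <- TRUE
    a <- graph$adj[[u]]
    if (is.null(a)) next
    for (r in seq_len(nrow(a))) {
      v <- a[r, 1]; w <- a[r, 2]
      if (done[v]) next   # finalized: re-relaxing could cycle predecessors
      nd <- dist[u] + w; nh <- hops[u] + 1
      better <- nd < dist[v] - 1e-12 ||
        (abs(nd - dist[v]) <= 1e-12 &&
           (nh < hops[v] || (nh == hops[v] && (is.na(prev[v]) || u < prev[v]))))
      if (better) { dist[v] <- nd; hops[v] <- nh; prev[v] <- u }
    }
  }
  if (!is.finite(dist[dst])) return(NULL)
  path <- dst
  while (path[1] != src) {
    if (length(path) > n) abort("predecessor cycle in shortest-path search",
                                "internal_error")
    path <- c(prev[path[1]], path)
  }
  list(path = path, weight = dist[dst])
}

#' Site residues defined by contact frequency with a chain
#'
#' Residues whose contact frequency with the named ligand or partner chain
#' is strictly greater than `threshold` across the trajectory (a residue
#' at exactly the threshold is excluded). A residue is "in contact" in a
#' frame if any of its heavy atoms is within the van der Waals criterion
#' of any heavy atom of the chain.
#'
#' @param traj a [Trajectory]
#' @param chain ligand or partner chain id
#' @param threshold frequency threshold, strict (default 0.60)
#' @param receptor_chains chains scanned; defaults to assigned protomers
#' @return data frame: chain, resno, resname, frequency
#' @export
define_site_residues <- function(traj, chain, threshold = 0.60,
                                 receptor_chains =
                                   names(traj$topology$protomer_map)) {
  if (!chain %in% traj$topology$atoms$chain)
    abort(paste("chain not in topology:", chain), "format_error")
  nf <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    m <- frame_model(traj, f)
    res <- ligand_contact_residues(m, chain, receptor_chains)
    if (!nrow(res)) next
    for (k in res_key(res$chain, res$resno))
      assign(k, (get0(k, envir = counts) %||% 0L) + 1L, envir = counts)
  }
  keys <- ls(counts)
  if (!length(keys))
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), frequency = numeric()))
  freq <- vapply(keys, get, numeric(1), envir = counts) / nf
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(chain = vapply(parts, `[`, "", 1),
                    resno = as.integer(vapply(parts, `[`, "", 2)),
                    frequency = freq, stringsAsFactors = FALSE)
  at <- traj$topology$atoms
  out$resname <- at$resname[match(res_key(out$chain, out$resno),
                                  atom_res_key(at))]
  out <- out[out$frequency > threshold, , drop = FALSE]
  out <- out[order(out$chain, out$resno), c("chain", "resno", "resname",
                                            "frequency")]
  rownames(out) <- NULL
  out
}

#' Highest-MI shortest pipelines between two residue sets
#'
#' For every (source, target) pair, finds the minimum-weight path
#' (Dijkstra; weights from [build_mi_graph()], so minimum weight =
#' highest MI). Pipelines are ranked by strength (sum of edge MI along the
#' path), ties broken by fewer residues then lexicographic residue order;
#' the `top_n` strongest are retained. Unreachable pairs are skipped and
#' counted.
#'
#' @param graph an `mi_graph`
#' @param sources,targets residue keys (`"chain|resno|"`) or data frames
#'   with chain/resno
#' @param top_n pipelines to retain
#' @return list of `AllostericPipeline`s (path keys, endpoints, strength,
#'   weight, rank), with attribute `n_unreachable`
#' @export
shortest_pipelines <- function(graph, sources, targets, top_n = 10) {
  as_keys <- function(s) {
    if (is.data.frame(s)) res_key(s$chain, s$resno,
                                  if ("icode" %in% names(s)) s$icode else "")
    else as.character(s)
  }
  src <- match(as_keys(sources), graph$nodes)
  tgt <- match(as_keys(targets), graph$nodes)
  if (anyNA(src) || anyNA(tgt))
    abort("source/target residues missing from graph", "configuration_error")
  if (!length(src) || !length(tgt))
    abort("source and target sets must be non-empty", "configuration_error")
  pipes <- list(); unreachable <- 0L
  for (s in src) for (t in tgt) {
    if (s == t) next
    r <- dijkstra_path(graph, s, t)
    if (is.null(r)) { unreachable <- unreachable + 1L; next }
    ## strength: sum of MI over consecutive path edges
    strength <- 0
    for (k in seq_len(length(r$path) - 1L))
      strength <- strength + graph$mi[r$path[k], r$path[k + 1L]]
    pipes[[length(pipes) + 1L]] <- list(
      path = graph$nodes[r$path], source = graph$nodes[s],
      target = graph$nodes[t], strength = strength, weight = r$weight)
  }
  if (length(pipes)) {
    strg <- vapply(pipes, `[[`, numeric(1), "strength")
    len <- vapply(pipes, function(p) length(p$path), 1L)
    lex <- vapply(pipes, function(p) paste(p$path, collapse = ">"), "")
    ord <- order(-strg, len, lex)
    pipes <- pipes[ord]
    pipes <- utils::head(pipes, top_n)
    for (k in seq_along(pipes)) pipes[[k]]$rank <- k
  }
  attr(pipes, "n_unreachable") <- unreachable
  class(pipes) <- "pipeline_list"
  pipes
}

#' Per-residue hubscores
#'
#' The hubscore of a residue is the number of retained pipelines passing
#' through it (path endpoints included).
#'
#' @param pipelines a `pipeline_list` from [shortest_pipelines()]
#' @param top_n rows reported in the `top` table (default 10)
#' @return a `HubScoreTable`: data frame residue, hubscore (sorted
#'   decreasing, ties lexicographic), with attribute `top`
#' @export
hubscores <- function(pipelines, top_n = 10) {
  if (!length(pipelines)) abort("need at least one pipeline",
                                "configuration_error")
  tally <- table(unlist(lapply(pipelines, `[[`, "path")))
  out <- data.frame(residue = names(tally),
                    hubscore = as.integer(tally), stringsAsFactors = FALSE)
  out <- out[order(-out$hubscore, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("HubScoreTable", class(out))
  attr(out, "top") <- utils::head(out, top_n)
  out
}

#' Export an MI graph as GraphML
#' @param graph an `mi_graph`
#' @param path output path
#' @export
write_graphml <- function(graph, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             '  <key id="mi" for="edge" attr.name="mi" attr.type="double"/>',
             '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
             '  <graph id="mi_network" edgedefault="undirected">',
             sprintf('    <node id="%s"/>', esc(graph$nodes)))
  if (nrow(graph$edges))
    lines <- c(lines, sprintf(
      '    <edge source="%s" target="%s"><data key="mi">%.8g</data><data key="w">%.8g</data></edge>',
      esc(graph$nodes[graph$edges$from]), esc(graph$nodes[graph$edges$to]),
      graph$edges$mi, graph$edges$weight))
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}
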
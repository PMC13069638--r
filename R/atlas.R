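# Edge orders for the enumerations. The input node A carries no self-loop,
# so two-node circuits have 3 candidate edges and three-node circuits 8,
# each taking a weight w in {-1, 0, +1} (inhibition / absent / promotion).
edge_order_two <- matrix(c("A", "B",
                           "B", "A",
                           "B", "B"), ncol = 2, byrow = TRUE)
edge_order_three <- matrix(c("A", "B",
                             "A", "C",
                             "B", "A",
                             "B", "C",
                             "C", "A",
                             "C", "B",
                             "B", "B",
                             "C", "C"), ncol = 2, byrow = TRUE)

edge_order <- function(n_nodes) {
  if (n_nodes == 2) edge_order_two
  else if (n_nodes == 3) edge_order_three
  else stop("only two- and three-node spaces are enumerated")
}

#' Encode and decode signed topologies
#'
#' A topology is the vector of edge weights `w` in `{-1, 0, +1}` over the
#' fixed candidate-edge order (`A->B, B->A, B->B` for two nodes;
#' `A->B, A->C, B->A, B->C, C->A, C->B, B->B, C->C` for three). The integer
#' code is the base-3 value of `w + 1`, so `encode_topology()` and
#' [decode_topology()] are exact inverses.
#'
#' @param w integer vector of edge weights in `{-1, 0, 1}`.
#' @param code integer code.
#' @param n_nodes 2 or 3.
#' @return `encode_topology()`: an integer code; `decode_topology()`: the
#'   weight vector (named by `"src->tgt"`).
#' @export
encode_topology <- function(w) {
  if (!all(w %in% -1:1)) stop("weights must be in {-1, 0, 1}")
  as.integer(sum((w + 1) * 3^(seq_along(w) - 1)))
}

#' @rdname encode_topology
#' @export
decode_topology <- function(code, n_nodes = 3) {
  eo <- edge_order(n_nodes)
  ne <- nrow(eo)
  if (code < 0 || code >= 3^ne) stop("code out of range")
  code <- as.integer(code)
  w <- integer(ne)
  for (i in seq_len(ne)) {
    w[i] <- code %% 3L - 1L
    code <- code %/% 3L
  }
  names(w) <- paste0(eo[, 1], "->", eo[, 2])
  w
}

topology_adjacency <- function(w, n_nodes) {
  eo <- edge_order(n_nodes)
  nodes <- LETTERS[seq_len(n_nodes)]
  A <- matrix(0L, n_nodes, n_nodes, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(eo)))
    A[eo[i, 1], eo[i, 2]] <- w[i]
  A
}

has_path <- function(A, from = 1, to = nrow(A)) {
  B <- A != 0
  R <- B
  for (i in seq_len(nrow(A))) R <- (R | (R %*% B) > 0)
  R[from, to]
}

#' Enumerate all two-node signed circuits
#'
#' All 27 assignments of `{-1, 0, +1}` to the edges `A->B`, `B->A`, `B->B`
#' (the input node A has no self-loop).
#'
#' @return integer vector of 27 unique topology codes (attribute
#'   `n_nodes = 2`).
#' @export
enumerate_two_node <- function() {
  codes <- 0:(3^3 - 1)
  attr(codes, "n_nodes") <- 2L
  codes
}

#' Enumerate three-node signed circuits
#'
#' The full space assigns `{-1, 0, +1}` to 8 candidate edges (all ordered
#' pairs among input A, regulator B, output C, plus the B and C self-loops;
#' no A self-loop), i.e. `3^8 = 6561` circuits. `rule = "path_A_to_C"` keeps
#' circuits with a directed path from input to output (5346 circuits).
#' `rule = "paper_default"` currently applies the same input-to-output
#' reachability filter; the candidate space is configurable because published
#' three-node screens differ in their connectivity conventions.
#'
#' @param rule `"none"`, `"path_A_to_C"`, or `"paper_default"`.
#' @return integer vector of topology codes (attribute `n_nodes = 3`).
#' @export
enumerate_three_node <- function(rule = c("path_A_to_C", "none",
                                          "paper_default")) {
  rule <- match.arg(rule)
  codes <- 0:(3^8 - 1)
  if (rule != "none") {
    keep <- vapply(codes, function(cd) {
      has_path(topology_adjacency(decode_topology(cd, 3), 3), 1, 3)
    }, logical(1))
    codes <- codes[keep]
  }
  attr(codes, "n_nodes") <- 3L
  codes
}

#' Detect an incoherent feedforward loop
#'
#' A three-node code contains an IFFL when for some ordering of distinct
#' nodes (X, Y, Z) both a direct edge X -> Z and a two-step path X -> Y -> Z
#' exist and their net signs disagree:
#' `sign(X->Z) * sign(X->Y) * sign(Y->Z) = -1`. The canonical death-circuit
#' instance is RIP1 -> RIP3 (direct, +) against RIP1 -> C8 -| RIP3
#' (indirect, -).
#'
#' @param code three-node topology code.
#' @return list with `flag` and `witnesses` (data frame of X, Y, Z and the
#'   two path signs).
#' @export
detect_iffl <- function(code) {
  A <- topology_adjacency(decode_topology(code, 3), 3)
  nodes <- rownames(A)
  wit <- NULL
  for (x in 1:3) for (y in 1:3) for (z in 1:3) {
    if (length(unique(c(x, y, z))) < 3) next
    if (A[x, z] != 0 && A[x, y] != 0 && A[y, z] != 0 &&
        A[x, z] * A[x, y] * A[y, z] == -1) {
      wit <- rbind(wit, data.frame(
        X = nodes[x], Y = nodes[y], Z = nodes[z],
        direct_sign = A[x, z], indirect_sign = A[x, y] * A[y, z]))
    }
  }
  list(flag = !is.null(wit),
       witnesses = if (is.null(wit))
         data.frame(X = character(), Y = character(), Z = character(),
                    direct_sign = integer(), indirect_sign = integer())
       else wit)
}

# Build a parameterless circuit skeleton for a topology code. The input node
# receives the stimulation edge; nodes with no incoming activation (stimulus
# included) get the constitutive basal activation so inhibition-only
# regulation remains observable. Screens use the raw lumped-constant
# denominator (phi = a^n/(a^n + j)), the convention under which the sampled
# j range 1e-3..100 acts directly as the denominator constant.
topology_circuit <- function(code, n_nodes = attr(code, "n_nodes"),
                             basal_rate = 0.01, denominator = "j") {
  if (is.null(n_nodes)) n_nodes <- 3L
  w <- decode_topology(as.integer(code), n_nodes)
  eo <- edge_order(n_nodes)
  nodes <- LETTERS[seq_len(n_nodes)]
  keep <- w != 0
  edges <- data.frame(source = ".stim", target = "A", sign = 1,
                      k = 1, j = 0.5, n = 1, stringsAsFactors = FALSE)
  if (any(keep)) {
    edges <- rbind(edges, data.frame(
      source = eo[keep, 1], target = eo[keep, 2], sign = w[keep],
      k = 1, j = 0.5, n = 1, stringsAsFactors = FALSE))
  }
  has_act <- vapply(nodes, function(nd)
    any(edges$target == nd & edges$sign > 0), logical(1))
  nd <- data.frame(name = nodes, total = 1, d = 0.1,
                   basal = ifelse(has_act, 0, basal_rate),
                   stringsAsFactors = FALSE)
  circuit(nd, edges, input = "A", output = nodes[n_nodes], s = 1,
          denominator = denominator)
}

#' Exhaustive random-parameter screen over topologies
#'
#' For every topology code, draws `n_per_topology` Latin hypercube parameter
#' sets and counts those whose input-capacity dose response passes the
#' biphasic (BD) and emergence (ED) thresholds. A topology "achieves" BE
#' dynamics when at least `achieve_q` parameter sets pass. Checkpointing
#' writes one CSV of completed topologies that a resumed run picks up.
#'
#' @param codes topology codes (with `n_nodes` attribute, see the
#'   enumerators).
#' @param ranges a [sampling_ranges()] object (`n_samples` is overridden by
#'   `n_per_topology`).
#' @param n_per_topology parameter sets per topology.
#' @param dose_grid dose grid for the input node's total.
#' @param bd_threshold,ed_threshold,ed_window classifier settings.
#' @param achieve_q passing-set count required to call a topology achieving.
#' @param seed master seed; topology substreams are derived from it.
#' @param checkpoint optional CSV path for incremental results.
#' @param t_max,tol integration settings.
#' @return data frame (`atlas_nodes`): `code`, `E` (edge count), `n_pass`,
#'   `P_BE`, `se`, `achieved`, `iffl`.
#' @export
exhaustive_screen <- function(codes, ranges, n_per_topology = 1000,
                              dose_grid = seq(0, 1, length.out = 21),
                              bd_threshold = 0.01, ed_threshold = 5,
                              ed_window = 0.1, achieve_q = 1, seed = 1,
                              checkpoint = NULL, t_max = 500, tol = 1e-6) {
  if (!length(codes)) stop("no topology codes supplied")
  n_nodes <- attr(codes, "n_nodes")
  if (is.null(n_nodes)) n_nodes <- 3L
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read.csv(checkpoint)
    need <- c("code", "E", "n_pass", "P_BE", "se", "achieved", "iffl")
    if (!identical(names(done), need))
      stop("checkpoint file is malformed; refusing to resume from it")
  }
  out <- done
  todo <- setdiff(as.integer(codes), done$code)
  for (cd in todo) {
    circ <- topology_circuit(cd, n_nodes)
    rg <- ranges
    rg$n_samples <- as.integer(n_per_topology)
    rg$seed <- seed + (cd %% 1000003L)
    smp <- lhs_sample(circ, rg)
    res <- screen_be_batch(circ, smp, "A", circ$output, dose_grid,
                           window = ed_window, t_max = t_max, tol = tol)
    ok <- res$nonconv == 0
    pass <- ok & res$bd >= bd_threshold & res$peak > 0 &
      res$ed >= ed_threshold
    p <- sum(pass) / max(1, sum(ok))
    w <- decode_topology(cd, n_nodes)
    row <- data.frame(code = cd, E = sum(w != 0), n_pass = sum(pass),
                      P_BE = p, se = sqrt(p * (1 - p) / max(1, sum(ok))),
                      achieved = sum(pass) >= achieve_q,
                      iffl = if (n_nodes == 3) detect_iffl(cd)$flag else FALSE)
    out <- rbind(out, row)
    if (!is.null(checkpoint)) write.csv(out, checkpoint, row.names = FALSE)
  }
  out[order(out$code), ]
}

#' Minimal circuits of the achieving sub-clusters
#'
#' Clusters the achieving topologies by pairwise Hamming distance between
#' signed edge vectors (agglomerative, average linkage) and reports, per
#' cluster, the achieving topology with the fewest edges (ties broken by
#' higher `P_BE`, then lower code).
#'
#' @param atlas an [exhaustive_screen()] data frame restricted to (or
#'   containing) achieving rows.
#' @param k_clusters number of sub-clusters.
#' @param n_nodes 2 or 3.
#' @return data frame of minimal circuits with their cluster id, edge count,
#'   `P_BE`, and IFFL flag.
#' @export
minimal_circuits <- function(atlas, k_clusters = 3, n_nodes = 3) {
  ach <- atlas[atlas$achieved, , drop = FALSE]
  if (!nrow(ach)) stop("no achieving topologies")
  if (k_clusters > nrow(ach))
    stop("k_clusters exceeds the number of achieving topologies")
  W <- t(vapply(ach$code, decode_topology, integer(nrow(edge_order(n_nodes))),
                n_nodes = n_nodes))
  cl <- if (nrow(ach) == 1 || k_clusters == 1) rep(1L, nrow(ach)) else {
    hc <- hclust(dist(W, method = "manhattan"), method = "average")
    cutree(hc, k = k_clusters)
  }
  rows <- lapply(sort(unique(cl)), function(ci) {
    sub <- ach[cl == ci, , drop = FALSE]
    sub <- sub[order(sub$E, -sub$P_BE, sub$code), , drop = FALSE]
    cbind(cluster = ci, sub[1, , drop = FALSE])
  })
  do.call(rbind, rows)
}

#' Edge-addition analysis around a base circuit
#'
#' Re-screens the base topology with each absent edge added (both signs) and
#' reports the change in the probability of BE dynamics; optionally the
#' proportion of BE-passing sets that also show coexistent dynamics (CD) is
#' reported for each variant, which identifies the positive-feedback
#' additions that make coexistence robust.
#'
#' @param base_code achieving base topology code.
#' @param ranges a [sampling_ranges()] object.
#' @param n_per_topology parameter sets per variant.
#' @param include_cd evaluate the CD proportion on BE-passing sets (slower).
#' @param additions optional data frame (`edge` index into the candidate
#'   order, `sign`) restricting which additions are tried.
#' @param cd_n_starts,seed,dose_grid,... as in [exhaustive_screen()].
#' @return data frame: `edge`, `sign`, `code`, `P_BE`, `delta_P_BE`, and
#'   (with `include_cd`) `prop_CD`.
#' @export
edge_addition_analysis <- function(base_code, ranges, n_per_topology = 1000,
                                   include_cd = FALSE, additions = NULL,
                                   cd_n_starts = 20, seed = 1,
                                   dose_grid = seq(0, 1, length.out = 21),
                                   bd_threshold = 0.01, ed_threshold = 5,
                                   ed_window = 0.1, t_max = 500, tol = 1e-6) {
  n_nodes <- 3L
  w0 <- decode_topology(as.integer(base_code), n_nodes)
  eval_code <- function(cd) {
    circ <- topology_circuit(cd, n_nodes)
    rg <- ranges; rg$n_samples <- as.integer(n_per_topology)
    rg$seed <- seed + (cd %% 1000003L)
    smp <- lhs_sample(circ, rg)
    res <- screen_be_batch(circ, smp, "A", circ$output, dose_grid,
                           window = ed_window, t_max = t_max, tol = tol)
    ok <- res$nonconv == 0
    be <- ok & res$bd >= bd_threshold & res$peak > 0 & res$ed >= ed_threshold
    prop_cd <- NA_real_
    if (include_cd && any(be)) {
      idx <- which(be)
      cdflags <- vapply(idx, function(ii) {
        ci <- circuit_with_params(circ, as.numeric(smp[ii, ]))
        classify_coexistent(ci, "A", dose_grid, n_starts = cd_n_starts,
                            seed = seed + ii, t_max = t_max,
                            tol = tol, early_stop = TRUE)$flag
      }, logical(1))
      prop_cd <- mean(cdflags)
    }
    c(P_BE = sum(be) / max(1, sum(ok)), prop_CD = prop_cd)
  }
  base <- eval_code(as.integer(base_code))
  if (is.null(additions)) {
    absent <- which(w0 == 0)
    additions <- expand.grid(edge = absent, sign = c(1L, -1L))
  }
  rows <- lapply(seq_len(nrow(additions)), function(i) {
    w <- w0
    w[additions$edge[i]] <- additions$sign[i]
    cd <- encode_topology(w)
    v <- eval_code(cd)
    data.frame(edge = names(w0)[additions$edge[i]],
               sign = additions$sign[i], code = cd,
               P_BE = v[["P_BE"]], delta_P_BE = v[["P_BE"]] - base[["P_BE"]],
               prop_CD = v[["prop_CD"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "base") <- c(code = as.integer(base_code), base)
  out
}

#' Build the layered topological atlas
#'
#' Connects achieving topologies that differ by exactly one added edge into
#' a directed acyclic graph layered by edge count E, annotated with each
#' topology's `P_BE` and topological potential `-ln(P_BE)` (the Boltzmann
#' analogy: rarely-achieving topologies sit high on the landscape).
#'
#' @param atlas an [exhaustive_screen()] data frame (achieving rows are
#'   used).
#' @param n_nodes 2 or 3.
#' @return an [igraph][igraph::make_graph] directed graph; vertex attributes
#'   `code`, `E`, `P_BE`, `potential`.
#' @export
build_atlas <- function(atlas, n_nodes = 3) {
  ach <- atlas[atlas$achieved, , drop = FALSE]
  if (!nrow(ach)) stop("no achieving topologies")
  W <- t(vapply(ach$code, decode_topology, integer(nrow(edge_order(n_nodes))),
                n_nodes = n_nodes))
  edges <- NULL
  for (i in seq_len(nrow(ach))) for (jj in seq_len(nrow(ach))) {
    if (i == jj) next
    dif <- W[jj, ] - W[i, ]
    nz <- dif != 0
    if (sum(nz) == 1 && W[i, nz] == 0)  # j adds exactly one edge to i
      edges <- rbind(edges, c(i, jj))
  }
  g <- igraph::make_empty_graph(n = nrow(ach), directed = TRUE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$code <- ach$code
  igraph::V(g)$E <- ach$E
  igraph::V(g)$P_BE <- ach$P_BE
  igraph::V(g)$potential <- -log(pmax(ach$P_BE, .Machine$double.xmin))
  igraph::V(g)$name <- as.character(ach$code)
  g
}
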
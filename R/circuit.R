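#' Construct a signed regulatory circuit
#'
#' A circuit couples named protein nodes through signed Hill-type regulation
#' edges. Each node carries a total (expression) amount `total` on the
#' normalized 0--1 scale (1 = wild type), a basal deactivation rate `d`, and an
#' optional constitutive activation rate `basal`. Each edge carries a maximal
#' rate `k`, a half-saturation level `j`, an integer Hill coefficient `n`, and a
#' sign (+1 activation, -1 inhibition). The reserved source name `".stim"`
#' denotes the constant stimulation level `s` (e.g. TNF) acting through a
#' dedicated activation edge.
#'
#' The deterministic dynamics of the active amount `x_i` are
#' `dx_i/dt = sum(activating) k (T_i - x_i) phi(a) - sum(inhibiting) k x_i
#' phi(a) + basal_i (T_i - x_i) - d_i x_i` with
#' `phi(a) = a^n / (a^n + j^n)`. The capacity factor `(T_i - x_i)` and the
#' proportional inhibition/decay terms make the box `[0, T]` forward-invariant
#' without any clipping.
#'
#' @param nodes data frame with columns `name`, and optionally `total`
#'   (default 1), `d` (default 0.1), `basal` (default 0).
#' @param edges data frame with columns `source`, `target`, `sign`, `k`, `j`,
#'   `n`. `source` may be `".stim"`.
#' @param input,output names of the input (stimulus-receiving / dose) node and
#'   the readout node.
#' @param s constant stimulation level in `[0, 1]`.
#' @param denominator `"jn"` uses `j^n` in the regulation-strength denominator
#'   so that `j` is an EC50 on the concentration scale for every Hill
#'   coefficient; `"j"` uses the raw lumped constant.
#' @return an object of class `circuit`.
#' @export
circuit <- function(nodes, edges, input, output, s = 1,
                    denominator = c("jn", "j")) {
  denominator <- match.arg(denominator)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$total)) nodes$total <- 1
  if (is.null(nodes$d)) nodes$d <- 0.1
  if (is.null(nodes$basal)) nodes$basal <- 0
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  obj <- structure(
    list(nodes = nodes[, c("name", "total", "d", "basal")],
         edges = edges, input = input, output = output, s = s,
         denominator = denominator),
    class = "circuit")
  validate_circuit(obj)
  obj
}

#' Validate a circuit object
#'
#' Checks node/edge well-formedness: unique node names, totals in `[0, 1]`,
#' positive deactivation rates, at most one signed edge per ordered node pair,
#' positive `k` and `j`, integer Hill coefficients, and existing input/output
#' nodes. Called by [circuit()]; exported for use after manual edits.
#'
#' @param x a `circuit`.
#' @return `x`, invisibly; errors describe the offending node or edge.
#' @export
validate_circuit <- function(x) {
  nodes <- x$nodes; edges <- x$edges
  if (anyDuplicated(nodes$name)) stop("duplicate node names")
  if (any(nodes$total < 0 | nodes$total > 1))
    stop("node totals must lie in [0, 1]")
  if (any(nodes$d <= 0)) stop("deactivation rates d must be positive")
  if (any(nodes$basal < 0)) stop("basal activation rates must be >= 0")
  if (nrow(edges)) {
    need <- c("source", "target", "sign", "k", "j", "n")
    miss <- setdiff(need, names(edges))
    if (length(miss)) stop("edges missing columns: ", paste(miss, collapse = ", "))
    bad <- !(edges$source %in% c(nodes$name, ".stim"))
    if (any(bad)) stop("unknown edge source: ", edges$source[which(bad)[1]])
    if (!all(edges$target %in% nodes$name))
      stop("unknown edge target: ",
           edges$target[which(!(edges$target %in% nodes$name))[1]])
    if (!all(edges$sign %in% c(-1, 1))) stop("edge sign must be +1 or -1")
    key <- paste(edges$source, edges$target)
    if (anyDuplicated(key))
      stop("more than one edge for pair: ", key[duplicated(key)][1])
    bad <- !is.finite(edges$k) | edges$k < 0
    if (any(bad))
      stop("edge ", edges$source[which(bad)[1]], " -> ",
           edges$target[which(bad)[1]], " has invalid k")
    if (any(!is.finite(edges$j) | edges$j <= 0)) stop("edge j must be positive")
    if (any(edges$n < 1 | edges$n != round(edges$n)))
      stop("Hill coefficient n must be a positive integer")
  }
  if (!(x$input %in% nodes$name)) stop("input node not found: ", x$input)
  if (!(x$output %in% nodes$name)) stop("output node not found: ", x$output)
  if (x$s < 0) stop("stimulation s must be >= 0")
  invisible(x)
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges; input=",
      x$input, " output=", x$output, " s=", format(x$s), "\n", sep = "")
  invisible(x)
}

node_index <- function(circ, name) {
  i <- match(name, circ$nodes$name)
  if (is.na(i)) stop("unknown node: ", name)
  i
}

# Low-level encoding consumed by the compiled engine.
encode_circuit <- function(circ) {
  e <- circ$edges
  list(d = as.numeric(circ$nodes$d),
       total = as.numeric(circ$nodes$total),
       basal = as.numeric(circ$nodes$basal),
       esrc = as.integer(ifelse(e$source == ".stim", 0L,
                                match(e$source, circ$nodes$name))),
       etgt = as.integer(match(e$target, circ$nodes$name)),
       esign = as.integer(e$sign),
       ek = as.numeric(e$k), ej = as.numeric(e$j), en = as.integer(e$n),
       s = as.numeric(circ$s),
       denom_jn = identical(circ$denominator, "jn"))
}

#' Modify node totals or edge parameters
#'
#' `set_total()` rescales a node's expression level (knockdown sets
#' `0 < total < 1`, knockout sets `total = 0`). `set_edge()` updates kinetic
#' parameters of an existing edge; setting `k = 0` silences the interaction
#' term while keeping the topology record intact.
#'
#' @param circ a `circuit`.
#' @param node,source,target node names.
#' @param total,k,j,n,sign new values (unnamed arguments are left unchanged).
#' @return the modified `circuit`.
#' @export
set_total <- function(circ, node, total) {
  circ$nodes$total[node_index(circ, node)] <- total
  validate_circuit(circ)
  circ
}

#' @rdname set_total
#' @export
set_edge <- function(circ, source, target, k = NULL, j = NULL, n = NULL,
                     sign = NULL) {
  i <- which(circ$edges$source == source & circ$edges$target == target)
  if (length(i) != 1) stop("no edge ", source, " -> ", target)
  if (!is.null(k)) circ$edges$k[i] <- k
  if (!is.null(j)) circ$edges$j[i] <- j
  if (!is.null(n)) circ$edges$n[i] <- n
  if (!is.null(sign)) circ$edges$sign[i] <- sign
  validate_circuit(circ)
  circ
}

#' Read or write a circuit model-specification YAML file
#'
#' The YAML layout mirrors the `circuit` object: `nodes` (list of `name`,
#' `total`, `d`, `basal`), `edges` (list of `source`, `target`, `sign`, `k`,
#' `j`, `n`), `input`, `output`, `s`, `denominator`.
#'
#' @param path file path.
#' @return [read_circuit_yaml()] returns a `circuit`;
#'   [write_circuit_yaml()] returns `path` invisibly.
#' @export
read_circuit_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  nodes <- do.call(rbind, lapply(y$nodes, function(n)
    data.frame(name = n$name,
               total = if (is.null(n$total)) 1 else n$total,
               d = if (is.null(n$d)) 0.1 else n$d,
               basal = if (is.null(n$basal)) 0 else n$basal,
               stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(y$edges, function(e) {
    # YAML 1.1 parses a bare key `n` as the boolean FALSE
    nval <- if (!is.null(e$n)) e$n else e[["FALSE"]]
    data.frame(source = e$source, target = e$target, sign = e$sign,
               k = e$k, j = e$j, n = nval, stringsAsFactors = FALSE)
  }))
  circuit(nodes, edges, input = y$input, output = y$output,
          s = if (is.null(y$s)) 1 else y$s,
          denominator = if (is.null(y$denominator)) "jn" else y$denominator)
}

#' @rdname read_circuit_yaml
#' @param circ a `circuit` to serialize.
#' @export
write_circuit_yaml <- function(circ, path) {
  y <- list(
    nodes = lapply(seq_len(nrow(circ$nodes)), function(i)
      as.list(circ$nodes[i, , drop = FALSE])),
    edges = lapply(seq_len(nrow(circ$edges)), function(i)
      as.list(circ$edges[i, , drop = FALSE])),
    input = circ$input, output = circ$output, s = circ$s,
    denominator = circ$denominator)
  yaml::write_yaml(y, path)
  invisible(path)
}
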
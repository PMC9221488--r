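#' @name rvine
#' @title Regular-vine copula construction
#'
#' @description
#' Sequential R-vine construction: the first tree is the maximum spanning
#' tree on absolute pairwise Kendall tau; each edge carries a fitted pair
#' copula; conditional pseudo-observations flow to the next tree through
#' h-functions; higher trees repeat the spanning-tree step among edges
#' allowed by the proximity condition (new edges may only join edges of
#' the previous tree that share a node), until two nodes and one edge
#' remain. The resulting density factorizes over all
#' \eqn{p(p-1)/2} pair copulas.
NULL

#' Maximum spanning tree (Prim)
#'
#' Maximum-weight spanning tree by Prim's algorithm with a deterministic
#' lexicographic tie-break: among equal-weight candidate edges the one
#' with the smallest (i, j) is taken.
#'
#' @param weights symmetric nonnegative weight matrix.
#' @param allowed optional logical matrix masking admissible edges.
#' @return integer matrix with two columns, one spanning-tree edge per
#'   row, each row sorted ascending.
#' @export
max_spanning_tree <- function(weights, allowed = NULL) {
  n <- nrow(weights)
  if (n != ncol(weights)) stop("weights must be square")
  if (n < 2) stop("need at least two nodes")
  if (is.null(allowed)) {
    allowed <- matrix(TRUE, n, n)
  }
  diag(allowed) <- FALSE
  intree <- c(1L)
  edges <- matrix(0L, 0, 2)
  while (length(intree) < n) {
    best <- NULL; best_w <- -Inf
    for (i in sort(intree)) {
      for (j in seq_len(n)) {
        if (j %in% intree || !allowed[i, j]) next
        w <- weights[i, j]
        a <- min(i, j); b <- max(i, j)
        if (w > best_w ||
            (w == best_w && (a < best[1] || (a == best[1] && b < best[2])))) {
          best_w <- w; best <- c(a, b); nxt <- j
        }
      }
    }
    if (is.null(best)) {
      comp <- paste(sort(intree), collapse = ",")
      stop("allowed edges do not connect the nodes; component {", comp,
           "} is isolated from {",
           paste(setdiff(seq_len(n), intree), collapse = ","), "}")
    }
    edges <- rbind(edges, best)
    intree <- c(intree, nxt)
  }
  dimnames(edges) <- NULL
  edges
}

# Conditioned pair / conditioning set of the edge joining two edges of
# the previous tree (proximity condition: they must share a node).
combine_edges <- function(e1, e2) {
  f1 <- c(e1$conditioned, e1$conditioning)
  f2 <- c(e2$conditioned, e2$conditioning)
  conditioning <- intersect(f1, f2)
  conditioned <- sort(c(setdiff(f1, f2), setdiff(f2, f1)))
  if (length(conditioned) != 2)
    stop("edges do not satisfy the proximity condition")
  list(conditioned = conditioned, conditioning = sort(conditioning))
}

# Conditional pseudo-observation F(x | full(e) \ {x}) cached on edge e.
edge_pseudo <- function(e, x) {
  if (x == e$conditioned[1]) e$cache_a
  else if (x == e$conditioned[2]) e$cache_b
  else stop("variable ", x, " not in the conditioned set of the edge")
}

independence_fit <- function(n) {
  pc <- pair_copula("independence")
  pc$loglik <- 0; pc$aic <- 0; pc$bic <- 0; pc$n_obs <- n
  pc
}

#' Build an R-vine copula from uniform data
#'
#' @param U numeric matrix with columns in (0, 1) (PIT series per channel).
#' @param candidates pair-copula family menu passed to
#'   [fit_pair_copula()].
#' @param criterion `"aic"` or `"bic"` edge-family selector.
#' @param trunc_level optional truncation: trees above this level get
#'   independence copulas without fitting (default: no truncation).
#' @return An object of class `vine_model` with `trees` (lists of edges,
#'   each holding `conditioned`, `conditioning`, `copula`), the first-tree
#'   Kendall matrix `tau1`, and total `loglik`/`aic`/`bic`.
#' @export
build_rvine <- function(U, candidates = default_candidates,
                        criterion = c("aic", "bic"), trunc_level = Inf) {
  criterion <- match.arg(criterion)
  U <- as.matrix(U)
  n <- nrow(U); p <- ncol(U)
  if (p < 2) stop("need at least two variables")
  if (n < 30) stop("need at least 30 observations")
  if (any(U <= 0 | U >= 1)) stop("U columns must lie strictly in (0, 1)")
  vnames <- colnames(U) %||% paste0("V", seq_len(p))
  sds <- apply(U, 2, stats::sd)
  if (any(sds < 1e-14))
    stop("constant column(s): ", paste(vnames[sds < 1e-14], collapse = ", "))

  taus <- tau_matrix(U, diag_value = 0)
  mst1 <- max_spanning_tree(abs(taus))
  tree1 <- lapply(seq_len(nrow(mst1)), function(i) {
    a <- mst1[i, 1]; b <- mst1[i, 2]
    pc <- fit_pair_copula(U[, a], U[, b], candidates, criterion)
    list(level = 1L, conditioned = c(a, b), conditioning = integer(0),
         node_a = a, node_b = b, copula = pc,
         cache_a = h_function(pc, U[, a], U[, b]),
         cache_b = h_function2(pc, U[, a], U[, b]))
  })
  trees <- list(tree1)

  for (j in seq_len(p - 1)[-1]) {
    prev <- trees[[j - 1]]
    m <- length(prev)
    ends <- lapply(prev, function(e) c(e$node_a, e$node_b))
    allowed <- matrix(FALSE, m, m)
    W <- matrix(0, m, m)
    specs <- vector("list", m * m); dim(specs) <- c(m, m)
    for (i in seq_len(m - 1)) {
      for (k in (i + 1):m) {
        if (length(intersect(ends[[i]], ends[[k]])) != 1) next
        allowed[i, k] <- allowed[k, i] <- TRUE
        sp <- combine_edges(prev[[i]], prev[[k]])
        x <- sp$conditioned[1]; y <- sp$conditioned[2]
        src_x <- if (x %in% prev[[i]]$conditioned) prev[[i]] else prev[[k]]
        src_y <- if (y %in% prev[[i]]$conditioned) prev[[i]] else prev[[k]]
        sp$px <- edge_pseudo(src_x, x)
        sp$py <- edge_pseudo(src_y, y)
        specs[[i, k]] <- sp
        if (j <= trunc_level)
          W[i, k] <- W[k, i] <- abs(empirical_kendall_tau(sp$px, sp$py))
      }
    }
    mst <- max_spanning_tree(W, allowed)
    trees[[j]] <- lapply(seq_len(nrow(mst)), function(r) {
      i <- mst[r, 1]; k <- mst[r, 2]
      sp <- specs[[i, k]]
      pc <- if (j > trunc_level) independence_fit(n)
            else fit_pair_copula(sp$px, sp$py, candidates, criterion)
      list(level = j, conditioned = sp$conditioned,
           conditioning = sp$conditioning, node_a = i, node_b = k,
           copula = pc,
           cache_a = h_function(pc, sp$px, sp$py),
           cache_b = h_function2(pc, sp$px, sp$py))
    })
  }

  # strip data caches from the stored model
  trees <- lapply(trees, function(tr) lapply(tr, function(e) {
    e$cache_a <- NULL; e$cache_b <- NULL; e
  }))
  ll <- sum(vapply(unlist(trees, recursive = FALSE),
                   function(e) e$copula$loglik, 0))
  k_tot <- sum(vapply(unlist(trees, recursive = FALSE),
                      function(e) length(e$copula$params), 0L))
  structure(list(n_vars = p, names = vnames, trees = trees,
                 tau1 = taus, n_obs = n, criterion = criterion,
                 loglik = ll, aic = -2 * ll + 2 * k_tot,
                 bic = -2 * ll + k_tot * log(n)),
            class = "vine_model")
}

#' @export
print.vine_model <- function(x, ...) {
  cat(sprintf("<vine_model> %d variables, %d trees, loglik %.2f (AIC %.2f)\n",
              x$n_vars, length(x$trees), x$loglik, x$aic))
  for (e in x$trees[[1]]) {
    cat(sprintf("  T1 %s-%s: %s%s tau=%.3f\n",
                x$names[e$conditioned[1]], x$names[e$conditioned[2]],
                e$copula$family,
                if (e$copula$rotation) paste0("(", e$copula$rotation, ")") else "",
                e$copula$tau))
  }
  invisible(x)
}

#' Assemble a vine model from a given first tree
#'
#' Builds a complete, proximity-valid `vine_model` whose first tree and
#' pair copulas are supplied and whose higher trees carry independence
#' copulas (a truncated, Markov-tree dependence). Used by the synthetic
#' scenario generator.
#'
#' @param edges integer matrix (two columns) of first-tree edges.
#' @param copulas list of [pair_copula()] objects, one per edge row.
#' @param p number of variables.
#' @param names optional variable names.
#' @return A `vine_model`.
#' @export
vine_from_tree1 <- function(edges, copulas, p, names = NULL) {
  if (nrow(edges) != p - 1) stop("a spanning tree on p nodes has p-1 edges")
  if (length(copulas) != nrow(edges)) stop("one copula per edge required")
  tree1 <- lapply(seq_len(nrow(edges)), function(i) {
    ab <- sort(as.integer(edges[i, ]))
    list(level = 1L, conditioned = ab, conditioning = integer(0),
         node_a = ab[1], node_b = ab[2], copula = copulas[[i]])
  })
  trees <- list(tree1)
  for (j in seq_len(p - 1)[-1]) {
    prev <- trees[[j - 1]]
    m <- length(prev)
    ends <- lapply(prev, function(e) c(e$node_a, e$node_b))
    allowed <- matrix(FALSE, m, m)
    for (i in seq_len(m - 1)) for (k in (i + 1):m)
      if (length(intersect(ends[[i]], ends[[k]])) == 1)
        allowed[i, k] <- allowed[k, i] <- TRUE
    mst <- max_spanning_tree(matrix(0, m, m), allowed)
    trees[[j]] <- lapply(seq_len(nrow(mst)), function(r) {
      i <- mst[r, 1]; k <- mst[r, 2]
      sp <- combine_edges(prev[[i]], prev[[k]])
      list(level = j, conditioned = sp$conditioned,
           conditioning = sp$conditioning, node_a = i, node_b = k,
           copula = independence_fit(NA_integer_))
    })
  }
  ll <- sum(vapply(tree1, function(e) e$copula$loglik %||% NA_real_, 0))
  structure(list(n_vars = p, names = names %||% paste0("V", seq_len(p)),
                 trees = trees, tau1 = NULL, n_obs = NA_integer_,
                 criterion = NA_character_, loglik = NA_real_,
                 aic = NA_real_, bic = NA_real_),
            class = "vine_model")
}

#' Validate R-vine structural invariants
#'
#' Checks edge counts per tree (tree j has `n_vars - j` edges), disjoint
#' conditioned/conditioning sets of the right sizes, and the proximity
#' condition.
#'
#' @param vm a `vine_model`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_rvine <- function(vm) {
  p <- vm$n_vars
  if (length(vm$trees) != p - 1) stop("expected ", p - 1, " trees")
  for (j in seq_along(vm$trees)) {
    tr <- vm$trees[[j]]
    if (length(tr) != p - j)
      stop("tree ", j, " must have ", p - j, " edges")
    for (e in tr) {
      if (length(e$conditioned) != 2 ||
          e$conditioned[1] == e$conditioned[2])
        stop("conditioned set must be a pair of distinct variables")
      if (length(e$conditioning) != j - 1)
        stop("conditioning set at tree ", j, " must have ", j - 1,
             " variables")
      if (length(intersect(e$conditioned, e$conditioning)))
        stop("conditioned and conditioning sets overlap")
      if (j > 1) {
        prev <- vm$trees[[j - 1]]
        ea <- prev[[e$node_a]]; eb <- prev[[e$node_b]]
        if (length(intersect(c(ea$node_a, ea$node_b),
                             c(eb$node_a, eb$node_b))) != 1)
          stop("proximity condition violated at tree ", j)
        sp <- combine_edges(ea, eb)
        if (!setequal(sp$conditioned, e$conditioned) ||
            !setequal(sp$conditioning, e$conditioning))
          stop("edge sets inconsistent with parents at tree ", j)
      }
    }
  }
  # tree 1 spans the variables
  g <- igraph::graph_from_edgelist(
    t(vapply(vm$trees[[1]], function(e) e$conditioned, c(1L, 2L))),
    directed = FALSE)
  if (igraph::vcount(g) < p || !igraph::is_connected(g))
    stop("tree 1 is not a spanning tree")
  invisible(TRUE)
}

# Recursive conditional CDFs over an evaluated vine.
# ucols: list of current per-variable uniforms; edges have eval caches.
make_cond_cdf <- function(vm, U) {
  memo <- new.env(parent = emptyenv())
  # index: key "x|sorted given" -> list(level, idx, dir)
  index <- new.env(parent = emptyenv())
  for (j in seq_along(vm$trees)) {
    for (i in seq_along(vm$trees[[j]])) {
      e <- vm$trees[[j]][[i]]
      k1 <- paste0(e$conditioned[1], "|",
                   paste(sort(c(e$conditioned[2], e$conditioning)),
                         collapse = ","))
      k2 <- paste0(e$conditioned[2], "|",
                   paste(sort(c(e$conditioned[1], e$conditioning)),
                         collapse = ","))
      assign(k1, list(j = j, i = i, dir = 1L), envir = index)
      assign(k2, list(j = j, i = i, dir = 2L), envir = index)
    }
  }
  condF <- function(x, given) {
    if (!length(given)) return(U[, x])
    key <- paste0(x, "|", paste(sort(given), collapse = ","))
    if (exists(key, envir = memo)) return(get(key, envir = memo))
    if (!exists(key, envir = index))
      stop("no edge provides F(", x, " | ",
           paste(sort(given), collapse = ","), ")")
    hit <- get(key, envir = index)
    e <- vm$trees[[hit$j]][[hit$i]]
    c1 <- e$conditioned[1]; c2 <- e$conditioned[2]
    a1 <- condF(c1, e$conditioning)
    a2 <- condF(c2, e$conditioning)
    val <- if (hit$dir == 1L) h_function(e$copula, a1, a2)
           else h_function2(e$copula, a1, a2)
    assign(key, val, envir = memo)
    val
  }
  condF
}

#' R-vine log density
#'
#' Log copula density on the uniform scale (marginal density terms are
#' excluded): the sum over all vine edges of the log pair-copula density
#' evaluated at the conditional pseudo-observations.
#'
#' @param vm a `vine_model`.
#' @param u a vector of length `n_vars` or a matrix with `n_vars` columns.
#' @return scalar (or vector of) log densities.
#' @export
vine_log_density <- function(vm, u) {
  U <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  if (ncol(U) != vm$n_vars) stop("u must have ", vm$n_vars, " columns")
  if (any(U <= 0 | U >= 1)) stop("u must lie strictly in (0, 1)")
  condF <- make_cond_cdf(vm, U)
  ld <- numeric(nrow(U))
  for (tr in vm$trees) {
    for (e in tr) {
      a1 <- condF(e$conditioned[1], e$conditioning)
      a2 <- condF(e$conditioned[2], e$conditioning)
      ld <- ld + log(pmax(copula_pdf(e$copula, a1, a2), 1e-300))
    }
  }
  ld
}

# Decompose the vine into sampling columns: the construction behind the
# R-vine matrix. Column k holds a variable x and, per tree level t, the
# partner variable and edge such that the edge's conditioning set equals
# the partners below level t.
vine_columns <- function(vm) {
  p <- vm$n_vars
  remaining <- lapply(vm$trees, function(tr) tr)
  vars_left <- seq_len(p)
  cols <- vector("list", p - 1)
  for (k in seq_len(p - 1)) {
    t_max <- p - k
    top <- remaining[[t_max]]
    if (length(top) != 1)
      stop("invalid vine: tree ", t_max, " should have one remaining edge")
    x <- min(top[[1]]$conditioned)
    partners <- integer(t_max)
    used <- vector("list", t_max)
    for (t in seq_len(t_max)) {
      hits <- which(vapply(remaining[[t]],
                           function(e) x %in% e$conditioned, TRUE))
      if (length(hits) != 1)
        stop("invalid vine: variable ", x,
             " must sit in exactly one conditioned set at tree ", t)
      e <- remaining[[t]][[hits]]
      if (t > 1 && !setequal(e$conditioning, partners[seq_len(t - 1)]))
        stop("invalid vine: conditioning sets are not nested along column")
      partners[t] <- setdiff(e$conditioned, x)
      used[[t]] <- e
      remaining[[t]][[hits]] <- NULL
    }
    vars_left <- setdiff(vars_left, x)
    cols[[k]] <- list(var = x, partners = partners, edges = used)
  }
  list(cols = cols, root = vars_left)
}

#' Sample from an R-vine copula
#'
#' Inverse-h-function (Rosenblatt) sampling along the vine's column
#' decomposition; deterministic given `seed`.
#'
#' @param vm a `vine_model`.
#' @param n number of rows to draw.
#' @param seed optional integer seed.
#' @return an `n x n_vars` matrix of uniforms distributed per `vm`.
#' @export
sample_rvine <- function(vm, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- vm$n_vars
  dec <- vine_columns(vm)
  W <- matrix(runif(n * p), n, p)
  U <- matrix(NA_real_, n, p)
  U[, dec$root] <- W[, dec$root]
  condF <- NULL
  for (k in rev(seq_len(p - 1))) {
    col <- dec$cols[[k]]
    x <- col$var
    condF <- make_cond_cdf(vm, U)  # rebuilt so new columns participate
    z <- W[, x]
    for (t in rev(seq_along(col$partners))) {
      given <- col$partners[seq_len(t - 1)]
      vc <- condF(col$partners[t], given)
      e <- col$edges[[t]]
      z <- if (x == e$conditioned[1]) h_inverse(e$copula, z, vc)
           else h_inverse2(e$copula, z, vc)
    }
    U[, x] <- z
  }
  colnames(U) <- vm$names
  U
}

#' Summarize the first vine tree
#'
#' Labels the first-tree edges by channel and modality, reports the core
#' nodes (all nodes attaining maximum degree) and the bridge edges that
#' connect an EEG channel to an EMG channel.
#'
#' @param vm a `vine_model`.
#' @param modalities character vector of `"EEG"`/`"EMG"` per variable.
#' @return list with `edges` (data frame), `core_nodes`, `bridges`.
#' @export
first_tree_summary <- function(vm, modalities) {
  p <- vm$n_vars
  if (length(modalities) != p) stop("one modality per variable required")
  ed <- t(vapply(vm$trees[[1]], function(e) e$conditioned, c(1L, 2L)))
  deg <- tabulate(c(ed), nbins = p)
  edges <- data.frame(
    from = vm$names[ed[, 1]], to = vm$names[ed[, 2]],
    from_modality = modalities[ed[, 1]], to_modality = modalities[ed[, 2]],
    family = vapply(vm$trees[[1]], function(e) e$copula$family, ""),
    tau = vapply(vm$trees[[1]], function(e) e$copula$tau, 0),
    stringsAsFactors = FALSE)
  edges$bridge <- edges$from_modality != edges$to_modality
  list(edges = edges,
       degree = stats::setNames(deg, vm$names),
       core_nodes = vm$names[deg == max(deg)],
       bridges = edges[edges$bridge, , drop = FALSE])
}
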
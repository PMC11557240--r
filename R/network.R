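#' Grow a directed interdependency network
#'
#' Networks are grown one node at a time from a two-node mutually dependent
#' seed.  Each newly added node connects inwards to one uniformly chosen
#' existing node (its dependee) and outwards to another (a dependent), so no
#' disconnected sub-network can arise during growth.  The inward and outward
#' targets are drawn independently and may coincide (producing a 2-cycle);
#' self-edges are impossible by construction, and a new node carries exactly
#' one edge in each direction so parallel edges cannot occur.
#'
#' Node ids are 0-based and follow insertion order (`0 .. n_nodes - 1`).
#'
#' @param n_nodes Number of nodes, at least 2.
#' @param rng_seed Integer seed; growth is fully deterministic given the seed.
#' @return A `dependency_network` object: a list with `n_nodes`, `seed_size`,
#'   `dependees` (per-node integer vectors of the nodes it depends on) and
#'   `dependents` (the inverse adjacency).
#' @examples
#' net <- grow_network(50, rng_seed = 1)
#' network_edges(net)
#' @export
grow_network <- function(n_nodes, rng_seed = 1) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || n_nodes < 2) {
    abort("`n_nodes` must be a single integer >= 2.", class = "coageing_invalid_size")
  }
  n_nodes <- as.integer(n_nodes)
  adj <- .grow_network_cpp(n_nodes, as.double(rng_seed))
  new_dependency_network(
    dependees = adj$dependees,
    dependents = adj$dependents,
    seed_size = 2L,
    rng_seed = rng_seed
  )
}

#' Construct a dependency network from explicit adjacency
#'
#' Low-level constructor used for hand-built test topologies (chains, motifs,
#' single-node networks).  `dependees[[i]]` lists the 0-based ids that node
#' `i - 1` depends on.  If `dependents` is omitted it is derived as the exact
#' inverse of `dependees`.
#'
#' @param dependees List of integer vectors (0-based ids), one per node.
#' @param dependents Optional inverse adjacency; derived when `NULL`.
#' @param seed_size Number of initial seed nodes (defaults to the full size
#'   for hand-built networks, for which growth invariants are not asserted).
#' @param rng_seed Seed recorded for provenance, or `NA`.
#' @return A `dependency_network`.
#' @export
new_dependency_network <- function(dependees, dependents = NULL,
                                   seed_size = length(dependees),
                                   rng_seed = NA_integer_) {
  n <- length(dependees)
  dependees <- lapply(dependees, as.integer)
  if (is.null(dependents)) {
    dependents <- vector("list", n)
    for (i in seq_len(n)) dependents[[i]] <- integer(0)
    for (i in seq_len(n)) {
      for (v in dependees[[i]]) {
        dependents[[v + 1L]] <- c(dependents[[v + 1L]], i - 1L)
      }
    }
  } else {
    dependents <- lapply(dependents, as.integer)
  }
  net <- structure(
    list(n_nodes = as.integer(n), seed_size = as.integer(seed_size),
         dependees = dependees, dependents = dependents,
         rng_seed = rng_seed),
    class = "dependency_network"
  )
  validate_network(net, grown = FALSE)
  net
}

#' Validate the structural invariants of a dependency network
#'
#' Checks that `dependees` and `dependents` are exact inverses, that there are
#' no self-edges, and (for grown networks) that every non-seed node has at
#' least one dependee and one dependent among lower-id nodes and that the
#' graph is weakly connected.
#'
#' @param net A `dependency_network`.
#' @param grown If `TRUE`, additionally assert the growth-time invariants.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net, grown = TRUE) {
  n <- net$n_nodes
  for (i in seq_len(n)) {
    if (any(net$dependees[[i]] == i - 1L) || any(net$dependents[[i]] == i - 1L)) {
      abort(sprintf("node %d has a self-edge", i - 1L))
    }
  }
  # inverse consistency
  fwd <- network_edges(net)
  # dependents[[v]] containing u means u depends on v: edge v -> u
  inv <- tibble(
    dependee = rep.int(0:(n - 1L), lengths(net$dependents)),
    dependent = unlist2int(net$dependents)
  )
  key_fwd <- sort(paste(fwd$dependee, fwd$dependent))
  key_inv <- sort(paste(inv$dependee, inv$dependent))
  if (!identical(key_fwd, key_inv)) {
    abort("`dependees` and `dependents` are not exact inverses")
  }
  if (grown) {
    s <- net$seed_size
    if (n > s) {
      for (i in (s + 1L):n) {
        id <- i - 1L
        if (!any(net$dependees[[i]] < id)) {
          abort(sprintf("grown node %d has no lower-id dependee", id))
        }
        if (!any(net$dependents[[i]] < id)) {
          abort(sprintf("grown node %d has no lower-id dependent", id))
        }
      }
    }
    if (!is_weakly_connected(net)) abort("network is not weakly connected")
  }
  invisible(net)
}

unlist2int <- function(x) {
  out <- unlist(x, use.names = FALSE)
  if (is.null(out)) integer(0) else as.integer(out)
}

is_weakly_connected <- function(net) {
  n <- net$n_nodes
  if (n <= 1) return(TRUE)
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    nbr[[i]] <- unique(c(net$dependees[[i]], net$dependents[[i]]))
  }
  seen <- logical(n)
  stack <- 0L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    for (w in nbr[[v + 1L]]) {
      if (!seen[w + 1L]) {
        seen[w + 1L] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

#' Edge list of a dependency network
#'
#' @param net A `dependency_network`.
#' @return A tibble with 0-based columns `dependee` and `dependent`, one row
#'   per directed dependency edge (the `dependent` depends on the `dependee`).
#' @export
network_edges <- function(net) {
  tibble(
    dependee = unlist2int(net$dependees),
    dependent = rep.int(0:(net$n_nodes - 1L), lengths(net$dependees))
  ) %>% arrange(.data$dependee, .data$dependent)
}

#' @export
print.dependency_network <- function(x, ...) {
  cat(sprintf("<dependency_network> %d nodes, %d edges (seed size %d)\n",
              x$n_nodes, sum(lengths(x$dependees)), x$seed_size))
  invisible(x)
}

#' Replicate a topology across a cohort
#'
#' `shared` returns `cohort_size` references to the one topology (all members
#' of a species share identical network structure); `randomized` regrows
#' independent topologies with the same number of nodes, mirroring the
#' convention of randomizing connectivity while keeping N constant.
#'
#' @param net A `dependency_network` (template; only its size is used in
#'   `randomized` mode).
#' @param mode `"shared"` or `"randomized"`.
#' @param cohort_size Number of copies, at least 1.
#' @param rng_seed Master seed for `randomized` regrowth.
#' @return A list of `cohort_size` networks.
#' @export
replicate_topology <- function(net, mode = c("shared", "randomized"),
                               cohort_size, rng_seed = 1) {
  mode <- match.arg(mode)
  if (cohort_size < 1) abort("`cohort_size` must be >= 1")
  if (mode == "shared") {
    rep(list(net), cohort_size)
  } else {
    lapply(seq_len(cohort_size), function(i) {
      grow_network(net$n_nodes, rng_seed = derive_seed(rng_seed, i, 0, 0))
    })
  }
}

#' Write / read a network as an edge-list text file
#'
#' One `dependee<TAB>dependent` pair per line (0-based ids) under a one-line
#' header, for reproducibility snapshots.
#'
#' @param net A `dependency_network`.
#' @param path File path.
#' @return `write_edgelist` returns `path` invisibly; `read_edgelist` returns
#'   a `dependency_network` (with `seed_size` unknown, recorded as the full
#'   size).
#' @export
write_edgelist <- function(net, path) {
  write.table(network_edges(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  ed <- read.table(path, header = TRUE, sep = "\t")
  n <- max(ed$dependee, ed$dependent) + 1L
  dependees <- vector("list", n)
  for (i in seq_len(n)) dependees[[i]] <- integer(0)
  for (k in seq_len(nrow(ed))) {
    v <- ed$dependent[k] + 1L
    dependees[[v]] <- c(dependees[[v]], as.integer(ed$dependee[k]))
  }
  new_dependency_network(dependees)
}

# CSR (0-based) form of the dependee adjacency, as consumed by the C++ engine
net_csr <- function(net) {
  list(
    ptr = as.integer(c(0L, cumsum(lengths(net$dependees)))),
    idx = unlist2int(net$dependees)
  )
}
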
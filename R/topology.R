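# Client / routing-server / central-server hierarchy and data partitioning.

#' Build a two-tier federation topology
#'
#' Clients are assigned to routing servers round-robin: router k receives
#' clients \{i : i mod n_routers = k\}. Deterministic; no randomness.
#'
#' @param n_clients Number of client nodes (>= 1).
#' @param n_routers Number of routing servers; default
#'   \code{ceiling(sqrt(n_clients))}. Must satisfy
#'   \code{1 <= n_routers <= n_clients}.
#' @return An object of class \code{"fl_topology"}: list with \code{clients}
#'   (each \code{client_id}, \code{router_id}, \code{shard}) and
#'   \code{routers} (each \code{router_id}, \code{client_ids}).
#' @export
build_topology <- function(n_clients, n_routers = ceiling(sqrt(n_clients))) {
  n_clients <- as.integer(n_clients)
  n_routers <- as.integer(n_routers)
  if (n_clients < 1L) stop("need at least one client")
  if (n_routers < 1L || n_routers > n_clients)
    stop("n_routers must lie in [1, n_clients]")
  ids <- seq_len(n_clients) - 1L
  clients <- lapply(ids, function(i)
    list(client_id = i, router_id = i %% n_routers, shard = character(0)))
  routers <- lapply(seq_len(n_routers) - 1L, function(k)
    list(router_id = k, client_ids = ids[ids %% n_routers == k]))
  structure(list(clients = clients, routers = routers, central_id = "SX"),
            class = "fl_topology")
}

#' @export
print.fl_topology <- function(x, ...) {
  cat("Federation topology:", length(x$clients), "clients,",
      length(x$routers), "routers, 1 central server\n")
  invisible(x)
}

n_clients_of <- function(topology) length(topology$clients)

client_ids_of <- function(topology) {
  vapply(topology$clients, function(cl) cl$client_id, integer(1))
}

# Dirichlet(alpha) draw via normalized gammas.
rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) <= 0) g <- rep(1, k)
  g / sum(g)
}

#' Partition training cases across clients
#'
#' Fills the \code{shard} of every client with case ids. Under the
#' \code{iid} scheme, cases are shuffled per class and dealt round-robin so
#' each client's class mix matches the pool. Under \code{label_skew}, each
#' client draws class proportions from a symmetric Dirichlet(skew_alpha)
#' and each class's cases are apportioned to clients by largest-remainder
#' on those proportions; small alpha concentrates classes on few clients.
#' Shards are disjoint and cover the pool. Any empty shard is re-balanced
#' by moving one case from the largest shard.
#'
#' @param cases Character case ids.
#' @param labels Class label per case.
#' @param topology An \code{fl_topology}.
#' @param scheme \code{"iid"} or \code{"label_skew"}.
#' @param skew_alpha Dirichlet concentration for \code{label_skew}.
#' @param seed Integer seed.
#' @return The topology with shards filled.
#' @export
partition_cases <- function(cases, labels, topology,
                            scheme = c("iid", "label_skew"),
                            skew_alpha = 0.5, seed = 1L) {
  scheme <- match.arg(scheme)
  nc <- n_clients_of(topology)
  if (length(cases) != length(labels)) stop("cases and labels differ in length")
  if (length(cases) < nc) stop("fewer training cases than clients")
  shards <- with_seed(seed, {
    sh <- rep(list(character(0)), nc)
    if (scheme == "iid") {
      offset <- 0L
      for (cl in unique(labels)) {
        members <- sample(cases[labels == cl])
        for (j in seq_along(members)) {
          tgt <- (offset + j - 1L) %% nc + 1L
          sh[[tgt]] <- c(sh[[tgt]], members[j])
        }
        offset <- offset + length(members)
      }
    } else {
      w <- t(vapply(seq_len(nc), function(i) rdirichlet1(3, skew_alpha),
                    numeric(3)))
      for (ci in seq_along(class_labels())) {
        cl <- class_labels()[ci]
        members <- sample(cases[labels == cl])
        if (!length(members)) next
        p <- w[, ci] / sum(w[, ci])
        counts <- largest_remainder(length(members), p)
        at <- 1L
        for (i in seq_len(nc)) {
          if (counts[i] > 0) {
            sh[[i]] <- c(sh[[i]], members[at:(at + counts[i] - 1L)])
            at <- at + counts[i]
          }
        }
      }
    }
    sh
  })
  # re-balance: an empty shard takes one case from the largest shard
  repeat {
    empties <- which(lengths(shards) == 0L)
    if (!length(empties)) break
    donor <- which.max(lengths(shards))
    if (lengths(shards)[donor] <= 1L)
      stop("cannot re-balance: no shard can donate a case")
    moved <- shards[[donor]][1L]
    shards[[donor]] <- shards[[donor]][-1L]
    shards[[empties[1L]]] <- moved
  }
  for (i in seq_len(nc)) topology$clients[[i]]$shard <- shards[[i]]
  topology
}

#' Serialize / restore a topology as JSON
#'
#' @param topology An \code{fl_topology}.
#' @param path File path.
#' @export
write_topology_json <- function(topology, path) {
  obj <- list(
    routers = lapply(topology$routers, function(r)
      list(router_id = r$router_id, client_ids = I(r$client_ids))),
    clients = lapply(topology$clients, function(cl)
      list(client_id = cl$client_id, router_id = cl$router_id,
           case_ids = I(cl$shard))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  clients <- lapply(obj$clients, function(cl)
    list(client_id = as.integer(cl$client_id),
         router_id = as.integer(cl$router_id),
         shard = as.character(unlist(cl$case_ids))))
  routers <- lapply(obj$routers, function(r)
    list(router_id = as.integer(r$router_id),
         client_ids = as.integer(unlist(r$client_ids))))
  structure(list(clients = clients, routers = routers, central_id = "SX"),
            class = "fl_topology")
}
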
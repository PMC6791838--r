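#' Estimated branch mass under a cylinder model
#'
#' `mass = density * pi * (median_thickness / 2)^2 * length`, converted from
#' mm^3 to cm^3. The default density, 0.7 g/cm^3, is in the typical range
#' of dry hardwood twigs and is configurable; masses are therefore
#' comparable between branches and across construction steps but are
#' estimates, not measurements.
#'
#' @param branch a [nest_branch] with positive length and thickness.
#' @param density_g_cm3 wood density, g/cm^3.
#' @return Mass in grams.
#' @export
branch_mass <- function(branch, density_g_cm3 = 0.7) {
  L <- branch$length
  d <- branch$median_thickness
  if (!isTRUE(L > 0) || !isTRUE(d > 0))
    stop("branch_mass needs positive length and median thickness")
  density_g_cm3 * pi * (d / 20)^2 * (L / 10)   # mm -> cm
}

#' Branch contact network
#'
#' Nodes are branches (centre point, median thickness, length, estimated
#' mass, scaffold flag); edges are contact points carrying their 3D
#' location. Contacts are stored undirected; the direction of assembly
#' emerges from the placement order chosen by the simulators.
#'
#' @param branches list of [nest_branch].
#' @param contacts contact data.frame from [detect_contacts()].
#' @param scaffold_ids branch ids forming the scaffold (may be empty and
#'   assigned later via [identify_scaffold()]).
#' @param density_g_cm3 wood density for the mass model.
#' @return A `contact_network` with data.frames `nodes` and `edges`.
#' @export
build_network <- function(branches, contacts, scaffold_ids = integer(0),
                          density_g_cm3 = 0.7) {
  ids <- vapply(branches, `[[`, 0L, "id")
  if (nrow(contacts) &&
      !all(c(contacts$branch_a, contacts$branch_b) %in% ids))
    stop("contact references a branch id that does not exist")
  centers <- t(vapply(branches, function(b) colMeans(b$pts), numeric(3)))
  nodes <- data.frame(
    id = ids,
    cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
    thickness = vapply(branches, `[[`, 0, "median_thickness"),
    length = vapply(branches, `[[`, 0, "length"),
    mass = vapply(branches, branch_mass, 0, density_g_cm3 = density_g_cm3),
    scaffold = ids %in% scaffold_ids)
  structure(list(nodes = nodes, edges = contacts), class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %d branches, %d contacts, %d scaffold, total mass %.1f g\n",
              nrow(x$nodes), nrow(x$edges), sum(x$nodes$scaffold),
              sum(x$nodes$mass)))
  invisible(x)
}

network_igraph <- function(net) {
  ig <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = as.character(net$nodes$id))
  if (nrow(net$edges)) {
    idx <- cbind(match(net$edges$branch_a, net$nodes$id),
                 match(net$edges$branch_b, net$nodes$id))
    ig <- igraph::add_edges(ig, t(idx))
  }
  ig
}

#' Write a contact network as GraphML plus a contacts CSV
#'
#' @param net a `contact_network`.
#' @param graphml_path GraphML output path.
#' @param contacts_csv optional CSV path for the contact list.
#' @export
write_network <- function(net, graphml_path, contacts_csv = NULL) {
  ig <- network_igraph(net)
  for (col in c("thickness", "length", "mass", "scaffold"))
    ig <- igraph::set_vertex_attr(ig, col, value = net$nodes[[col]])
  igraph::write_graph(ig, graphml_path, format = "graphml")
  if (!is.null(contacts_csv))
    write.csv(net$edges, contacts_csv, row.names = FALSE)
  invisible(graphml_path)
}

#' Identify the scaffold branches
#'
#' The scaffold is the set of thick anchor branches (in a tree-built nest,
#' those originating from the host tree): nodes whose median thickness is
#' at or above the given percentile of the thickness distribution,
#' restricted to the largest connected component among them. Explicit ids
#' override the heuristic. If the percentile selects nothing, the single
#' thickest branch (lowest id on ties) is used.
#'
#' @param network a `contact_network`.
#' @param thickness_percentile percentile in (0, 100), default 95.
#' @param override explicit scaffold id set (optional).
#' @return Integer vector of scaffold node ids.
#' @export
identify_scaffold <- function(network, thickness_percentile = 95,
                              override = NULL) {
  nodes <- network$nodes
  if (nrow(nodes) == 0) stop("empty network")
  if (!is.null(override)) {
    if (!all(override %in% nodes$id)) stop("override ids not in network")
    return(as.integer(override))
  }
  if (length(unique(nodes$thickness)) == 1)      # nothing to discriminate
    return(min(nodes$id))
  cut <- quantile(nodes$thickness, thickness_percentile / 100, names = FALSE)
  sel <- nodes$id[nodes$thickness >= cut]
  if (length(sel) == 0) {
    mx <- max(nodes$thickness)
    return(min(nodes$id[nodes$thickness == mx]))
  }
  if (length(sel) > 1) {
    ig <- network_igraph(network)
    sub <- igraph::induced_subgraph(ig, match(sel, nodes$id))
    comp <- igraph::components(sub)
    sizes <- comp$csize
    big <- which(sizes == max(sizes))[1]
    sel <- sel[comp$membership == big]
  }
  sort(as.integer(sel))
}

gravity_alignment <- function(contact_loc, center, gravity) {
  u <- contact_loc - center
  nu <- vec_norm(u)
  if (nu == 0) return(0)
  max(0, sum(u / nu * gravity / vec_norm(gravity)))
}

#' Support score of a candidate branch against the placed structure
#'
#' Sum, over all contacts between the candidate and already placed
#' branches, of the partner's median thickness weighted by the downward
#' alignment of the contact: `t_partner * max(0, g . u)` where `u` is the
#' unit vector from the candidate's centre to the contact location and `g`
#' points down. Contacts below the candidate's centre therefore support it;
#' contacts above contribute nothing. Zero when the candidate touches no
#' placed branch.
#'
#' @param candidate candidate branch id.
#' @param placed ids of already placed branches.
#' @param network a `contact_network`.
#' @param gravity unit gravity vector (default `c(0, 0, -1)`).
#' @return Non-negative support score.
#' @export
support_score <- function(candidate, placed, network,
                          gravity = c(0, 0, -1)) {
  ed <- network$edges
  if (nrow(ed) == 0 || length(placed) == 0) return(0)
  sel <- (ed$branch_a == candidate & ed$branch_b %in% placed) |
         (ed$branch_b == candidate & ed$branch_a %in% placed)
  if (!any(sel)) return(0)
  nd <- network$nodes
  center <- unlist(nd[nd$id == candidate, c("cx", "cy", "cz")])
  tot <- 0
  for (r in which(sel)) {
    partner <- if (ed$branch_a[r] == candidate) ed$branch_b[r] else ed$branch_a[r]
    t_p <- nd$thickness[nd$id == partner]
    loc <- c(ed$x[r], ed$y[r], ed$z[r])
    tot <- tot + t_p * gravity_alignment(loc, center, gravity)
  }
  tot
}

seq_result <- function(ids, network, strategy) {
  nd <- network$nodes
  mass <- nd$mass[match(ids, nd$id)]
  structure(data.frame(step = seq_along(ids), branch_id = ids, mass = mass,
                       cumulative_mass = cumsum(mass)),
            class = c("build_sequence", "data.frame"),
            strategy = strategy)
}

#' @export
print.build_sequence <- function(x, ...) {
  cat(sprintf("<build_sequence> '%s': %d steps, total mass %.1f g\n",
              attr(x, "strategy"), nrow(x),
              x$cumulative_mass[nrow(x)]))
  invisible(x)
}

tie_order <- function(ids, network) {
  nd <- network$nodes
  ids[order(-nd$thickness[match(ids, nd$id)], ids)]
}

#' Simulate the 'Greedy' construction strategy
#'
#' Placement starts with the scaffold (by descending thickness); then, at
#' every step, the unplaced branch with the greatest support from the
#' already placed structure is added. Ties go to the thicker branch, then
#' the lower id. When no remaining branch has positive support, the
#' tie-break alone decides (descending thickness), so disconnected stragglers
#' end up appended by thickness.
#'
#' @param network a `contact_network`.
#' @param gravity unit gravity vector (default `c(0, 0, -1)`).
#' @param scaffold_ids scaffold ids; defaults to [identify_scaffold()].
#' @return A `build_sequence` data.frame: step, branch_id, mass,
#'   cumulative_mass, with attribute `strategy = "greedy"`.
#' @export
simulate_greedy <- function(network, gravity = c(0, 0, -1),
                            scaffold_ids = NULL) {
  if (is.null(scaffold_ids)) scaffold_ids <- identify_scaffold(network)
  order_ids <- tie_order(scaffold_ids, network)
  remaining <- setdiff(network$nodes$id, order_ids)
  while (length(remaining)) {
    scores <- vapply(remaining, support_score, 0, placed = order_ids,
                     network = network, gravity = gravity)
    best <- max(scores)
    cands <- remaining[scores == best]
    pick <- tie_order(cands, network)[1]
    order_ids <- c(order_ids, pick)
    remaining <- setdiff(remaining, pick)
  }
  seq_result(order_ids, network, "greedy")
}

contact_support_weights <- function(network, gravity) {
  # per-contact support weight: summed partner thickness scaled by the
  # better of the two downward alignments at the contact location
  nd <- network$nodes
  ed <- network$edges
  vapply(seq_len(nrow(ed)), function(r) {
    ca <- unlist(nd[nd$id == ed$branch_a[r], c("cx", "cy", "cz")])
    cb <- unlist(nd[nd$id == ed$branch_b[r], c("cx", "cy", "cz")])
    loc <- c(ed$x[r], ed$y[r], ed$z[r])
    align <- max(gravity_alignment(loc, ca, gravity),
                 gravity_alignment(loc, cb, gravity))
    ta <- nd$thickness[nd$id == ed$branch_a[r]]
    tb <- nd$thickness[nd$id == ed$branch_b[r]]
    (ta + tb) * align
  }, 0)
}

max_support_tree <- function(network, gravity) {
  # maximum-support spanning forest over the load-bearing contacts only:
  # contacts with zero downward alignment cannot hold anything and are not
  # part of the minimum viable skeleton
  ig <- network_igraph(network)
  if (nrow(network$edges) == 0) return(ig)
  w <- contact_support_weights(network, gravity)
  ig <- igraph::delete_edges(ig, which(w <= 0))
  w <- w[w > 0]
  if (length(w) == 0) return(ig)
  igraph::mst(ig, weights = max(w) + 1 - w)   # maximum-weight spanning forest
}

#' Simulate the 'Gradual' construction strategy
#'
#' Phase 1 erects a minimum viable skeleton: the maximum-support spanning
#' tree over the load-bearing contacts (contacts with positive downward
#' alignment), covering every branch reachable from the scaffold through
#' such contacts, placed in breadth-first order from the scaffold. Phase 2
#' enriches the skeleton with the remaining branches in order of increasing
#' support (recomputed each step) among those touching the placed
#' structure; branches never reachable through any contact are appended by
#' descending thickness at the end.
#'
#' @inheritParams simulate_greedy
#' @return A `build_sequence` with attribute `strategy = "gradual"`; the ids
#'   placed in phase 1 are attached as attribute `phase1`.
#' @export
simulate_gradual <- function(network, gravity = c(0, 0, -1),
                             scaffold_ids = NULL) {
  if (is.null(scaffold_ids)) scaffold_ids <- identify_scaffold(network)
  nd <- network$nodes
  tree <- max_support_tree(network, gravity)
  order_ids <- tie_order(scaffold_ids, network)
  for (root in order_ids) {
    bfs <- igraph::bfs(tree, root = match(as.character(root),
                                          igraph::V(tree)$name),
                       unreachable = FALSE, order = TRUE)
    bfs_ids <- as.integer(igraph::V(tree)$name[as.integer(bfs$order)])
    bfs_ids <- bfs_ids[!is.na(bfs_ids)]
    order_ids <- unique(c(order_ids, bfs_ids))
  }
  phase1 <- order_ids
  # phase 2: branches outside the load-bearing skeleton, least-supported
  # first among those already touching the placed structure
  remaining <- setdiff(nd$id, order_ids)
  while (length(remaining)) {
    touch <- vapply(remaining, function(b)
      any((network$edges$branch_a == b & network$edges$branch_b %in% order_ids) |
          (network$edges$branch_b == b & network$edges$branch_a %in% order_ids)),
      logical(1))
    if (!any(touch)) break
    cands <- remaining[touch]
    sc <- vapply(cands, support_score, 0, placed = order_ids,
                 network = network, gravity = gravity)
    low <- min(sc)
    pick <- tie_order(cands[sc == low], network)[1]
    order_ids <- c(order_ids, pick)
    remaining <- setdiff(remaining, pick)
  }
  stragglers <- setdiff(nd$id, order_ids)
  if (length(stragglers)) order_ids <- c(order_ids, tie_order(stragglers, network))
  out <- seq_result(order_ids, network, "gradual")
  attr(out, "phase1") <- phase1
  out
}

#' Cumulative mass curve of a build sequence
#'
#' @param seq a `build_sequence`.
#' @return data.frame `step, branch_id, mass, cumulative_mass` (the running
#'   total of estimated branch masses).
#' @export
mass_curve <- function(seq) {
  as.data.frame(seq)[, c("step", "branch_id", "mass", "cumulative_mass")]
}

#' Write a build sequence as CSV
#'
#' @param seq a `build_sequence`.
#' @param path CSV output path.
#' @export
write_sequence <- function(seq, path) {
  df <- mass_curve(seq)
  df$strategy <- attr(seq, "strategy")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
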
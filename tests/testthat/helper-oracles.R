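# Independent oracles the implementation is checked against. These stay
# deliberately naive: boolean matrix powers for shortest paths, truth-table
# enumeration for gene-rule expansion, a literal step-up for BH, a
# character walk for formula atom counts.

# All-pairs shortest path edge counts by boolean matrix powers.
oracle_edge_distances <- function(graph) {
  nodes <- graph$nodes$node_id
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges) > 0) {
    A[cbind(match(graph$edges$from, nodes), match(graph$edges$to, nodes))] <- 1
  }
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  P <- diag(n)
  for (k in seq_len(n)) {
    P <- (P %*% A) > 0
    storage.mode(P) <- "double"
    D[P > 0 & D == Inf] <- k
  }
  D
}

# Enzyme-rooted forest from the oracle distances: reaction-step distance is
# (edge count + 1) / 2 on the bipartite graph; upstream uses paths INTO the
# root.
oracle_forest <- function(graph) {
  D <- oracle_edge_distances(graph)
  mets <- graph$nodes$node_id[graph$nodes$node_type == "metabolite"]
  roots <- graph$nodes$node_id[graph$nodes$node_type == "enzyme"]
  rows <- lapply(roots, function(r) {
    down <- unname((D[r, mets] + 1) / 2)
    up <- unname((D[mets, r] + 1) / 2)
    as_int <- function(x) {
      out <- rep(NA_integer_, length(x))
      out[is.finite(x)] <- as.integer(x[is.finite(x)])
      out
    }
    tibble::tibble(
      root_id = r, species_id = mets,
      down_distance = as_int(down),
      up_distance = as_int(up)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[!(is.na(out$down_distance) & is.na(out$up_distance)), ]
  out[order(out$root_id, out$species_id, method = "radix"), ]
}

# Evaluate a gene-reaction rule string with R's own parser (independent of
# the package's recursive-descent parser).
oracle_gpr_eval <- function(gpr, assignment) {
  expr <- gsub("\\bAND\\b", "&&", gsub("\\bOR\\b", "||", gpr,
                                       ignore.case = TRUE),
               ignore.case = TRUE)
  eval(parse(text = expr), envir = as.list(assignment))
}

dnf_eval <- function(disjuncts, assignment) {
  any(vapply(disjuncts, function(genes) all(unlist(assignment[genes])),
             logical(1)))
}

# Literal BH step-up: sort, scale by n/rank, cumulative min from the top,
# cap at 1, return in input order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Regex-free atom count: walk the characters once.
atom_count_walk <- function(f) {
  chars <- strsplit(f, "")[[1]]
  total <- 0L
  i <- 1L
  while (i <= length(chars)) {
    stopifnot(grepl("[A-Z]", chars[i]))
    i <- i + 1L
    if (i <= length(chars) && grepl("[a-z]", chars[i])) i <- i + 1L
    num <- ""
    while (i <= length(chars) && grepl("[0-9]", chars[i])) {
      num <- paste0(num, chars[i])
      i <- i + 1L
    }
    total <- total + if (num == "") 1L else as.integer(num)
  }
  total
}

# Classical pooled two-sample t per column of a wide abundance table.
pooled_t_oracle <- function(abundance, design, contrast) {
  m <- as.matrix(abundance[, setdiff(names(abundance), "sample")])
  rownames(m) <- abundance$sample
  g <- design$group[match(abundance$sample, design$sample)]
  x1 <- m[g == contrast[1], , drop = FALSE]
  x2 <- m[g == contrast[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  s2 <- ((n1 - 1) * apply(x1, 2, var) + (n2 - 1) * apply(x2, 2, var)) /
    (n1 + n2 - 2)
  (colMeans(x1) - colMeans(x2)) / sqrt(s2 * (1 / n1 + 1 / n2))
}
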
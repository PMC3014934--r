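# shared fixture builders: everything is generated in code at test time

random_alignment <- function(n_taxa, n_sites, seed = 1,
                             missing_frac = 0) {
  set.seed(seed)
  pool <- aa_alphabet()
  m <- matrix(sample(pool, n_taxa * n_sites, replace = TRUE),
              nrow = n_taxa,
              dimnames = list(paste0("tax", seq_len(n_taxa)), NULL))
  if (missing_frac > 0) {
    hit <- runif(length(m)) < missing_frac
    m[hit] <- sample(c("-", "X", "?"), sum(hit), replace = TRUE)
  }
  aa_alignment(m)
}

random_tree <- function(n_tips, seed = 1, rooted = FALSE) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = rooted,
                   tip.label = paste0("t", seq_len(n_tips)))
  tr$edge.length <- round(runif(nrow(tr$edge), 0.05, 0.8), 4)
  tr
}

balanced_5taxon_tree <- function(inner = 0.1, outer = 0.2) {
  parse_newick(sprintf("((A:%g,B:%g):%g,(C:%g,D:%g):%g,E:%g);",
                       outer, outer, inner, outer, outer, inner, outer))
}

# brute-force site log-likelihood by exhaustive internal-state enumeration
brute_site_loglik <- function(aln, tree, model) {
  tr <- reorder(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  aa <- aa_alphabet()
  cls <- phylodissect:::model_classes(model)
  out <- numeric(ncol(aln))
  for (s in seq_len(ncol(aln))) {
    tot <- 0
    for (cl in cls) {
      P <- lapply(seq_len(nrow(tr$edge)), function(e) {
        cl$V %*% (exp(cl$lambda * tr$edge.length[e] * cl$rate) * cl$Vinv)
      })
      internal <- (nt + 1):nn
      states <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
      lik <- 0
      for (r in seq_len(nrow(states))) {
        st <- integer(nn)
        st[internal] <- states[r, ]
        pr <- cl$pi[st[nt + 1]]
        for (e in seq_len(nrow(tr$edge))) {
          p <- tr$edge[e, 1]; u <- tr$edge[e, 2]
          if (u <= nt) {
            k <- match(aln[tr$tip.label[u], s], aa)
            pr <- pr * if (is.na(k)) 1 else P[[e]][st[p], k]
          } else {
            pr <- pr * P[[e]][st[p], st[u]]
          }
        }
        lik <- lik + pr
      }
      tot <- tot + cl$weight * lik
    }
    out[s] <- log(tot)
  }
  out
}

lg1 <- function() build_model("LG", alpha = 1, k = 1)
lg4 <- function() build_model("LG", alpha = 0.5, k = 4)
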
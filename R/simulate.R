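BASES <- c("A", "C", "G", "T")
TS_PARTNER <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T

#' Simulation configuration
#'
#' Parameters of the CpG-island sequence-evolution simulator.  The
#' substitution process is HKY-like (transition/transversion ratio
#' \code{kappa}) with a context-dependent boost: the C->T transition
#' of a C followed by G, and the G->A transition of a G preceded by C,
#' are multiplied by \code{lambda}, reproducing the elevated
#' deamination rate of methylatable CpG dinucleotides on both strands.
#' At \code{lambda = 1} the process reduces exactly to the
#' context-free one.
#'
#' @param tree Newick string (or \code{phylo}) with branch lengths;
#'   with \code{mu} in substitutions/site/My, branch lengths are My.
#' @param seq_length root sequence length (even).
#' @param cpg_fraction fraction of nonoverlapping dinucleotide
#'   positions planted as CpG at the root (in [0, 0.5)).
#' @param mu baseline substitution rate per site per unit branch
#'   length.
#' @param lambda fold excess of CpG deamination transitions (>= 1;
#'   biologically motivated range 10-50).
#' @param kappa transition/transversion rate ratio for the
#'   context-free process.
#' @param seed integer seed driving the whole simulation.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(tree, seq_length = 27000, cpg_fraction = 0.18,
                       mu = 3e-4, lambda = 20, kappa = 2, seed = 1) {
  if (inherits(tree, "phylo")) tree <- ape::write.tree(tree)
  stopifnot(is.character(tree), length(tree) == 1)
  if (seq_length %% 2 != 0 || seq_length < 2)
    stop("seq_length must be a positive even number")
  if (cpg_fraction < 0 || cpg_fraction >= 0.5)
    stop("cpg_fraction must be in [0, 0.5)")
  if (lambda < 1) stop("lambda must be >= 1")
  if (!is.finite(mu) || mu <= 0 || !is.finite(kappa) || kappa <= 0)
    stop("mu and kappa must be positive and finite")
  structure(list(tree = tree, seq_length = as.integer(seq_length),
                 cpg_fraction = cpg_fraction, mu = mu, lambda = lambda,
                 kappa = kappa, seed = as.integer(seed)),
            class = "sim_config")
}

#' Hominid study preset
#'
#' Seven-taxon tree
#' \code{(((((human,(neanderthal,denisovan)),(chimp,bonobo)),gorilla),orangutan)}
#' with node ages (My): neanderthal-denisovan 0.43, human vs that pair
#' 0.65, chimp-bonobo 1.7, human-chimp 5, gorilla 8, orangutan 14 --
#' the divergence times of the hominid literature.  Sequence length
#' 27,000 and CpG fraction 0.18 match the composition of concatenated
#' housekeeping-gene CpG islands; the default rate mu = 3e-4
#' subs/site/My puts pairwise identities in the observed 97-100% band.
#'
#' @inheritParams sim_config
#' @return an object of class \code{sim_config}.
#' @export
hominid_preset <- function(seq_length = 27000, cpg_fraction = 0.18,
                           mu = 3e-4, lambda = 20, kappa = 2, seed = 1) {
  nwk <- paste0(
    "((((human:0.65,(neanderthal:0.43,denisovan:0.43):0.22):4.35,",
    "(chimp:1.7,bonobo:1.7):3.3):3,gorilla:8):6,orangutan:14);")
  sim_config(nwk, seq_length = seq_length, cpg_fraction = cpg_fraction,
             mu = mu, lambda = lambda, kappa = kappa, seed = seed)
}

#' Generate the root CpG-island-like sequence
#'
#' CpG dinucleotides are planted at randomly chosen nonoverlapping
#' even offsets until \code{cpg_fraction} of the dinucleotide frame is
#' CpG; the background is GC-rich (60% GC) but drawn so that no CG
#' dinucleotide occurs outside the planted set, making the planted
#' positions the exact ground truth for site classification.
#' Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{sim_config}.
#' @return character string of length \code{seq_length} with attribute
#'   \code{cpg_starts}: the 1-based first columns of the planted CpGs.
#' @export
generate_root <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$seq_length
  n_pos <- L %/% 2L
  n_cpg <- floor(n_pos * cfg$cpg_fraction)
  frame_starts <- seq.int(1L, L - 1L, by = 2L)
  planted <- sort(sample(frame_starts, n_cpg))
  # background with 60% GC, no CG dinucleotide anywhere
  p <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)
  s <- integer(L)
  s[1] <- sample.int(4L, 1L, prob = p)
  pg <- p; pg["G"] <- 0  # after a C, never draw G
  for (i in 2:L)
    s[i] <- sample.int(4L, 1L, prob = if (s[i - 1] == 2L) pg else p)
  s[planted] <- 2L
  s[planted + 1L] <- 3L
  out <- paste(BASES[s], collapse = "")
  attr(out, "cpg_starts") <- planted
  out
}

# per-site extra rate from CpG context; position i is boosted when it
# is the C of a CpG or the G of a CpG
cpg_extra <- function(s, mu, kappa, lambda) {
  L <- length(s)
  w_ts <- kappa / (kappa + 2)
  boost <- mu * w_ts * (lambda - 1)
  extra <- numeric(L)
  cpg_c <- which(s[-L] == 2L & s[-1] == 3L)
  extra[cpg_c] <- boost
  extra[cpg_c + 1L] <- boost
  extra
}

# evolve one sequence along one branch; returns list(seq, events)
simulate_branch <- function(s, t_len, cfg, branch_label) {
  L <- length(s)
  mu <- cfg$mu; kappa <- cfg$kappa; lambda <- cfg$lambda
  w_ts <- kappa / (kappa + 2)
  extra <- cpg_extra(s, mu, kappa, lambda)
  rate <- mu + extra
  ev_site <- integer(0); ev_from <- integer(0); ev_to <- integer(0)
  ev_time <- numeric(0); ev_ctx <- logical(0)
  if (t_len > 0) {
    total <- sum(rate)
    if (!is.finite(total)) stop("non-finite total substitution rate")
    tnow <- stats::rexp(1, total)
    while (tnow <= t_len) {
      i <- sample.int(L, 1L, prob = rate)
      b <- s[i]
      in_cpg <- extra[i] > 0
      w <- rep(1, 4)
      w[b] <- 0
      w[TS_PARTNER[b]] <- kappa * (if (in_cpg) lambda else 1)
      to <- sample.int(4L, 1L, prob = w)
      ev_site <- c(ev_site, i); ev_from <- c(ev_from, b)
      ev_to <- c(ev_to, to); ev_time <- c(ev_time, tnow)
      ev_ctx <- c(ev_ctx, in_cpg)
      s[i] <- to
      # CpG context only changes for the pairs touching site i
      lo <- max(1L, i - 1L); hi <- min(L, i + 1L)
      for (j in lo:hi) {
        is_c <- s[j] == 2L && j < L && s[j + 1L] == 3L
        is_g <- s[j] == 3L && j > 1L && s[j - 1L] == 2L
        extra[j] <- if (is_c || is_g) mu * w_ts * (lambda - 1) else 0
        rate[j] <- mu + extra[j]
      }
      tnow <- tnow + stats::rexp(1, sum(rate))
    }
  }
  events <- data.frame(branch = rep(branch_label, length(ev_site)),
                       site = ev_site, time = ev_time,
                       from = BASES[ev_from], to = BASES[ev_to],
                       cpg_context = ev_ctx, stringsAsFactors = FALSE)
  list(seq = s, events = events)
}

#' Simulate sequence evolution along a tree
#'
#' Gillespie simulation along every branch of \code{cfg$tree},
#' starting from [generate_root()].  No indels are introduced, so the
#' leaf sequences form a gap-free alignment whose columns are
#' homologous by construction and the classification ground truth is
#' exact.  Per-branch random substreams are derived deterministically
#' from the global seed.
#'
#' @param cfg a \code{sim_config}.
#' @return An object of class \code{sim_result}: list with
#'   \code{alignment} (\code{cpg_aln}), \code{true_tree}
#'   (\code{phylo}), \code{events} (data.frame with branch, site,
#'   time, from, to, cpg_context), \code{root_seq} (with planted CpG
#'   starts as attribute) and \code{config}.
#' @export
evolve <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tr <- ape::read.tree(text = cfg$tree)
  if (is.null(tr$edge.length))
    stop("simulation tree needs branch lengths")
  root_seq <- generate_root(cfg)
  s_root <- match(strsplit(root_seq, "")[[1]], BASES)
  ntip <- ape::Ntip(tr)
  node_label <- function(v)
    if (v <= ntip) tr$tip.label[v] else paste0("node", v)

  seqs <- vector("list", ntip + tr$Nnode)
  seqs[[ntip + 1L]] <- s_root
  ord <- ape::reorder.phylo(tr, "cladewise")
  all_events <- vector("list", nrow(ord$edge))
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    set.seed((cfg$seed %% 100000L) * 20011L + e * 7919L)
    res <- simulate_branch(seqs[[parent]], ord$edge.length[e], cfg,
                           node_label(child))
    seqs[[child]] <- res$seq
    all_events[[e]] <- res$events
  }
  rows <- vapply(seq_len(ntip),
                 function(v) paste(BASES[seqs[[v]]], collapse = ""),
                 character(1))
  aln <- new_alignment(tr$tip.label, rows)
  events <- do.call(rbind, all_events)
  structure(list(alignment = aln, true_tree = tr, events = events,
                 root_seq = root_seq, config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated alignment:", length(x$alignment$taxa), "taxa x",
      x$alignment$n_cols, "columns;", nrow(x$events), "events\n")
  invisible(x)
}

#' Replay an event log from the root
#'
#' Reconstructs every leaf sequence by applying the logged events edge
#' by edge down the tree.  Used to verify event-log conservation: the
#' replayed alignment must equal the simulated one exactly.
#'
#' @param sim a \code{sim_result}.
#' @return a \code{cpg_aln} reconstructed purely from root sequence,
#'   tree and event log.
#' @export
replay_events <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  tr <- ape::reorder.phylo(sim$true_tree, "cladewise")
  ntip <- ape::Ntip(tr)
  node_label <- function(v)
    if (v <= ntip) tr$tip.label[v] else paste0("node", v)
  seqs <- vector("list", ntip + tr$Nnode)
  seqs[[ntip + 1L]] <- match(strsplit(sim$root_seq, "")[[1]], BASES)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    s <- seqs[[parent]]
    ev <- sim$events[sim$events$branch == node_label(child), , drop = FALSE]
    if (nrow(ev) > 0) {
      ev <- ev[order(ev$time), , drop = FALSE]
      for (r in seq_len(nrow(ev))) {
        if (BASES[s[ev$site[r]]] != ev$from[r])
          stop("event log inconsistent at ", node_label(child),
               " site ", ev$site[r])
        s[ev$site[r]] <- match(ev$to[r], BASES)
      }
    }
    seqs[[child]] <- s
  }
  rows <- vapply(seq_len(ntip),
                 function(v) paste(BASES[seqs[[v]]], collapse = ""),
                 character(1))
  new_alignment(tr$tip.label, rows)
}
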
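# Small in-code fixtures shared across test files.

# constructs table: one clone per protein unless clones > 1
make_constructs <- function(proteins, clones = 1L, is_control = FALSE,
                            is_kinase_dead = FALSE) {
  grid <- expand.grid(protein_id = proteins, clone = seq_len(clones),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    construct_id = sprintf("%s_c%d", grid$protein_id, grid$clone),
    protein_id = grid$protein_id,
    orf_clone = sprintf("ORF_%s_%d", grid$protein_id, grid$clone),
    vector = "nls",
    is_control = rep_len(is_control, nrow(grid)),
    is_kinase_dead = rep_len(is_kinase_dead, nrow(grid)))
}

# long kinase-condition matrix from a score vector recycled over the grid
make_matrix <- function(proteins, strains, conditions, scores) {
  grid <- expand.grid(protein_id = proteins, strain = strains,
                      condition_id = conditions, stringsAsFactors = FALSE)
  tibble::tibble(protein_id = grid$protein_id, strain = grid$strain,
                 condition_id = grid$condition_id,
                 score = as.integer(rep_len(scores, nrow(grid))))
}

# condition table with all strains evaluated
make_conditions <- function(condition_ids, strains) {
  out <- tibble::tibble(condition_id = condition_ids,
                        treatment = paste0("t_", condition_ids),
                        additive = "none", concentration = 1, unit = "x",
                        temperature = 30)
  for (s in strains) out[[paste0("evaluated_", s)]] <- TRUE
  out
}

retained_all <- function(matrix) {
  dplyr::distinct(matrix, condition_id, strain)
}

# independent pair-counting rank-sum oracle: U by direct pair enumeration,
# exact p by enumerating all subset assignments of the pooled values
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

oracle_ranksum_p <- function(x, y, alternative = "two_sided") {
  pooled <- c(x, y)
  nx <- length(x)
  mu <- nx * length(y) / 2
  idx <- utils::combn(length(pooled), nx)
  u_all <- apply(idx, 2, function(S) oracle_u(pooled[S], pooled[-S]))
  u_obs <- oracle_u(x, y)
  eps <- 1e-9
  switch(alternative,
    two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps),
    greater = mean(u_all >= u_obs - eps),
    less = mean(u_all <= u_obs + eps))
}

# brute-force upset oracle: loop over every distinct pair and test membership
oracle_upset <- function(sets) {
  key <- function(p, c) paste(p, c, sep = "\r")
  by_strain <- split(key(sets$protein_id, sets$condition_id), sets$strain)
  all_pairs <- unique(key(sets$protein_id, sets$condition_id))
  combos <- vapply(all_pairs, function(k) {
    member <- names(by_strain)[vapply(by_strain, function(s) k %in% s, logical(1))]
    paste(sort(member), collapse = "+")
  }, character(1))
  tab <- table(combos)
  tibble::tibble(combination = names(tab), count = as.integer(tab))
}

# brute-force severe-breadth oracle
oracle_severe_hist <- function(matrix, retained) {
  m <- dplyr::semi_join(matrix, retained, by = c("condition_id", "strain"))
  kin <- unique(m$protein_id)
  breadth <- vapply(kin, function(p) {
    sub <- m[m$protein_id == p & m$score >= 3L, ]
    length(unique(sub$strain))
  }, integer(1))
  breadth <- breadth[breadth > 0L]
  tab <- table(breadth)
  tibble::tibble(n_strains = as.integer(names(tab)),
                 n_kinases = as.integer(tab))
}

# random small defect-pair fixture for concordance property tests
random_concordance_fixture <- function(n_proteins = 12, n_conditions = 6,
                                       strains = c("A", "B", "C")) {
  make_matrix(sprintf("P%02d", seq_len(n_proteins)), strains,
              sprintf("c%d", seq_len(n_conditions)),
              sample(0:3, n_proteins * n_conditions * length(strains),
                     replace = TRUE, prob = c(0.5, 0.2, 0.15, 0.15)))
}
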
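#!/usr/bin/env Rscript
# Stage 4: annotate candidates against the bait/control interaction survey,
# drop clusters dominated by nonspecific interactors, diffuse heat from the
# phenotype seeds (t = 0.25) over the weighted Laplacian, and rank the
# candidates. The planted seed module should surface at the top.

library(bioidnet)

fix <- function(f) file.path("results/fixtures", f)
net <- prune_unconnected(read_edge_list(fix("edges.tsv"), 0.4))
clusters <- mcl_cluster(net)
nodes <- igraph::V(net)$name

specificity <- annotate_specificity(nodes, read_specificity(fix("specificity.tsv")))
message(sprintf("specificity classes: %s",
                paste(names(table(specificity)), table(specificity),
                      sep = "=", collapse = ", ")))
retained <- exclude_nonspecific_clusters(clusters, specificity)
message(sprintf("%d/%d clusters retained after the nonspecific filter",
                length(retained$clusters), length(clusters$clusters)))

seeds <- read_seeds(fix("seeds.txt"))
diff <- heat_diffuse(net, seeds, t = 0.25)
differential <- utils::read.delim("results/differential.tsv")
candidates <- differential$protein_id[differential$candidate == 1]
ranked <- rank_candidates(diff, intersect(candidates, nodes), top_k = 30,
                          clusters = clusters, specificity = specificity)
ranked$is_seed <- as.integer(ranked$is_seed)
utils::write.table(ranked, "results/ranked_candidates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

dtab <- diff
dtab$is_seed <- as.integer(dtab$is_seed)
dtab$cluster_id <- unname(clusters$membership[dtab$node])
dtab$specificity <- unname(specificity[dtab$node])
utils::write.table(dtab, "results/diffusion.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(fix("truth.json"), simplifyVector = TRUE)
memb <- unlist(truth$network_truth$membership)
h <- stats::setNames(diff$heat, diff$node)
block_heat <- tapply(unname(h[names(memb)]), memb, mean)
message("mean heat per planted block (block = seed block first):")
print(round(block_heat[order(-block_heat)], 4))
message(sprintf("top of the ranking: %s",
                paste(utils::head(ranked$node, 5), collapse = ", ")))
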
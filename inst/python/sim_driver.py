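"""Coalescent simulation driver for the introClust R package.

Reads an explicit job specification (JSON) produced by the R side,
simulates a four-taxon chromosome with msprime (ancestry with
recombination and an optional timed migration window, HKY mutations),
writes a VCF, and emits raw ground-truth material as JSON:

  - site counts (variable / bi-allelic / multi-allelic among the samples)
  - pairwise per-site divergence (dxy) between species
  - the union of genomic intervals whose ancestry crossed between P2 and
    P3 through a migration event (for any sampled lineage)
  - per-local-tree trio topology runs for one haploid genome per species
  - the number of distinct local trees (recombination-unbroken segments)

All scientific summarisation (tract merging, fractions, scaling) happens
on the R side; this script only adapts the spec to msprime/tskit calls.

Usage: python sim_driver.py job.json
"""

import json
import sys

import numpy as np
import msprime
import tskit


def build_demography(spec):
    dem = msprime.Demography()
    for pop in spec["populations"]:
        dem.add_population(name=pop["name"], initial_size=pop["size"])
    for sp in sorted(spec["splits"], key=lambda e: e["time"]):
        dem.add_population_split(time=sp["time"], derived=list(sp["derived"]),
                                 ancestral=sp["ancestral"])
    mig = spec["migration"]
    if mig["rate"] > 0:
        a, b = mig["between"]
        # backwards in time: switch on at the recent window edge,
        # off again at the old edge (the P1/P2 divergence)
        dem.add_symmetric_migration_rate_change(
            time=mig["start"], populations=[a, b], rate=mig["rate"])
        dem.add_symmetric_migration_rate_change(
            time=mig["end"], populations=[a, b], rate=0)
    dem.sort_events()
    return dem


def simulate(spec):
    dem = build_demography(spec)
    samples = [msprime.SampleSet(s["n"], population=s["population"],
                                 time=s["time"], ploidy=2)
               for s in spec["samples"]]
    ts = msprime.sim_ancestry(
        samples=samples, demography=dem,
        sequence_length=spec["L"], recombination_rate=spec["r"],
        record_migrations=spec["migration"]["rate"] > 0,
        random_seed=spec["seed"])
    mut = spec["mutation"]
    model = msprime.HKY(kappa=mut["kappa"])
    mts = msprime.sim_mutations(ts, rate=mut["mu"], model=model,
                                random_seed=spec["seed"] + 1)
    if mut.get("rateScaling") == "branch_rate" and mut["p2RateScale"] != 1:
        mts = scale_p2_mutations(mts, mut, spec)
    return mts


def p2_edge_mutations(ts, pop_id):
    """Mutation ids whose edge lies on a lineage residing in P2."""
    pops = ts.tables.nodes.population
    muts = ts.tables.mutations
    return np.nonzero(pops[muts.node] == pop_id)[0]


def scale_p2_mutations(ts, mut, spec):
    """Direct branch-rate alternative to the sampling-time work-around.

    s < 1: thin mutations on P2-resident edges to a fraction s.
    s > 1: overlay an extra pass at rate (s-1)*mu and keep only its
    mutations on P2-resident edges. Lineage residence is approximated by
    the population of the node below each mutation's edge, which is exact
    without migration.
    """
    s = mut["p2RateScale"]
    pop_id = next(p.id for p in ts.populations()
                  if (p.metadata or {}).get("name") == "P2")
    rng = np.random.default_rng(spec["seed"] + 2)
    if s < 1:
        tables = ts.dump_tables()
        cand = p2_edge_mutations(ts, pop_id)
        drop = cand[rng.random(cand.size) > s]
        keep = np.setdiff1d(np.arange(ts.num_mutations), drop)
        keep_mutations(tables, keep)
        return tables.tree_sequence()
    extra = msprime.sim_mutations(
        ts, rate=(s - 1) * mut["mu"], model=msprime.HKY(kappa=mut["kappa"]),
        random_seed=spec["seed"] + 3, keep=False)
    tables = extra.dump_tables()
    keep_mutations(tables, p2_edge_mutations(extra, pop_id))
    extra_only = tables.tree_sequence()
    merged = msprime.sim_mutations(
        extra_only, rate=mut["mu"], model=msprime.HKY(kappa=mut["kappa"]),
        random_seed=spec["seed"] + 1, keep=True)
    return merged


def keep_mutations(tables, keep_ids):
    muts = tables.mutations.copy()
    tables.mutations.clear()
    keep = np.zeros(muts.num_rows, dtype=bool)
    keep[keep_ids] = True
    site_used = np.zeros(tables.sites.num_rows, dtype=bool)
    for i in range(muts.num_rows):
        if keep[i]:
            row = muts[i]
            tables.mutations.append(row.replace(parent=tskit.NULL))
            site_used[row.site] = True
    # drop sites left without mutations
    sites = tables.sites.copy()
    tables.sites.clear()
    new_id = np.full(sites.num_rows, -1, dtype=np.int64)
    j = 0
    for i in range(sites.num_rows):
        if site_used[i]:
            tables.sites.append(sites[i])
            new_id[i] = j
            j += 1
    m = tables.mutations.copy()
    tables.mutations.clear()
    for i in range(m.num_rows):
        tables.mutations.append(m[i].replace(site=int(new_id[m[i].site])))
    tables.sort()
    tables.build_index()
    tables.compute_mutation_parents()
    return tables


def species_sample_sets(ts):
    order = ["P1", "P2", "P3", "P4"]
    name_of = {}
    for pop in ts.populations():
        md = pop.metadata or {}
        name_of[pop.id] = md.get("name", str(pop.id))
    sets = {name: [] for name in order}
    for node_id in ts.samples():
        name = name_of[ts.node(node_id).population]
        if name in sets:
            sets[name].append(int(node_id))
    return [sets[name] for name in order]


def site_counts(ts):
    if ts.num_sites == 0:
        return 0, 0, 0
    G = ts.genotype_matrix()
    G.sort(axis=1)
    nall = (np.diff(G, axis=1) > 0).sum(axis=1) + 1
    variable = int((nall >= 2).sum())
    multi = int((nall > 2).sum())
    bi = int((nall == 2).sum())
    return variable, bi, multi


def migrant_intervals(ts, spec):
    """Union of intervals whose ancestry crossed between P2 and P3."""
    mig = spec["migration"]
    if mig["rate"] == 0 or ts.num_migrations == 0:
        return []
    names = {}
    for pop in ts.populations():
        md = pop.metadata or {}
        names[pop.id] = md.get("name", str(pop.id))
    want = set(mig["between"])
    iv = [(m.left, m.right) for m in ts.migrations()
          if {names[m.source], names[m.dest]} == want]
    if not iv:
        return []
    iv.sort()
    merged = [list(iv[0])]
    for left, right in iv[1:]:
        if left <= merged[-1][1]:
            merged[-1][1] = max(merged[-1][1], right)
        else:
            merged.append([left, right])
    return merged


def topology_runs(ts):
    """Per-local-tree trio topology for one haploid genome per species."""
    sets = species_sample_sets(ts)
    nodes = [s[0] for s in sets]  # first haplotype of the first individual
    if ts.num_migrations > 0:     # simplify() cannot carry migration records
        tables = ts.dump_tables()
        tables.migrations.clear()
        ts = tables.tree_sequence()
    sub = ts.simplify(samples=nodes, filter_populations=False)
    # in the simplified ts the four samples are 0..3 in P1..P4 order
    labels = {frozenset([0, 1]): "P1P2", frozenset([0, 2]): "P1P3",
              frozenset([1, 2]): "P2P3"}
    runs = []
    for tree in sub.trees():
        t12 = tree.tmrca(0, 1)
        t13 = tree.tmrca(0, 2)
        t23 = tree.tmrca(1, 2)
        tmin = min(t12, t13, t23)
        if t12 == tmin:
            topo = "P1P2"
        elif t13 == tmin:
            topo = "P1P3"
        else:
            topo = "P2P3"
        runs.append([tree.interval.left, tree.interval.right, topo])
    return runs


def local_time_trees(ts, k):
    """Newick local trees (one haploid per species) at k equally spaced
    positions, branch lengths in generations."""
    sets = species_sample_sets(ts)
    nodes = [s[0] for s in sets]
    if ts.num_migrations > 0:
        tables = ts.dump_tables()
        tables.migrations.clear()
        ts = tables.tree_sequence()
    sub = ts.simplify(samples=nodes, filter_populations=False)
    labels = {i: "P%d" % (i + 1) for i in range(4)}
    out = []
    L = sub.sequence_length
    for j in range(k):
        tree = sub.at((j + 0.5) * L / k)
        out.append(tree.as_newick(node_labels=labels))
    return out


def main(job_path):
    with open(job_path) as fh:
        spec = json.load(fh)
    ts = simulate(spec)
    if spec.get("vcf"):
        n_dip = sum(s["n"] for s in spec["samples"])
        names = []
        for s in spec["samples"]:
            names += ["%s_%d" % (s["population"], i) for i in range(s["n"])]
        with open(spec["vcf"], "w") as fh:
            # 0-based tskit coordinates -> 1-based VCF positions
            ts.write_vcf(fh, contig_id=spec.get("contig", "chr1"),
                         individual_names=names,
                         position_transform=lambda x: np.asarray(x) + 1)
    if spec.get("trees"):
        ts.dump(spec["trees"])
    if spec.get("truth"):
        variable, bi, multi = site_counts(ts)
        sets = species_sample_sets(ts)
        K = len(sets)
        pairs = [(i, j) for i in range(K) for j in range(i + 1, K)]
        dxy = ts.divergence(sets, indexes=pairs, mode="site")
        truth = {
            "L": spec["L"],
            "n_sites": int(ts.num_sites),
            "n_variable": variable,
            "n_biallelic": bi,
            "n_multiallelic": multi,
            "n_trees": int(ts.num_trees),
            "dxy_pairs": [["P%d" % (i + 1), "P%d" % (j + 1)]
                          for i, j in pairs],
            "dxy": [float(x) for x in np.atleast_1d(dxy)],
            "migrant_intervals": migrant_intervals(ts, spec),
            "topology_runs": topology_runs(ts),
        }
        k = int(spec.get("local_trees", 0) or 0)
        if k > 0:
            truth["local_trees"] = local_time_trees(ts, k)
        with open(spec["truth"], "w") as fh:
            json.dump(truth, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv[1]))
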
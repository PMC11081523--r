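// Core graph machinery for fragment mining:
//  - molecule graphs with typed atoms (element, formal charge, aromatic flag)
//    and typed bonds (order, aromatic flag),
//  - perception of the smallest ring(s) through every ring bond,
//  - enumeration of connected, ring-complete subgraphs (units = bridge bonds
//    and minimal rings; a subgraph is ring-complete when every ring bond it
//    contains brings along at least one minimal ring of the parent molecule),
//  - a canonical code for small labelled graphs (used to deduplicate
//    candidates across molecules and DFS paths),
//  - a VF2-style subgraph monomorphism matcher for support counting and
//    fragment/molecule matching.
//
// Hydrogens are implicit throughout: all graphs are heavy-atom graphs.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <functional>
#include <array>
#include <map>
#include <set>
#include <string>
#include <vector>
#include <queue>

using namespace Rcpp;

namespace {

struct Graph {
  int n = 0;
  std::vector<int> elem, charge;
  std::vector<char> arom;
  // edges: a, b (0-based), label (0 = aromatic, otherwise bond order)
  std::vector<std::array<int, 3> > edges;
  std::vector<std::vector<std::pair<int, int> > > adj;  // (neighbour, edge id)

  void build_adj() {
    adj.assign(n, {});
    for (int e = 0; e < (int)edges.size(); ++e) {
      adj[edges[e][0]].push_back({edges[e][1], e});
      adj[edges[e][1]].push_back({edges[e][0], e});
    }
  }
};

Graph graph_from_list(const List& g) {
  Graph m;
  IntegerVector elem = g["elem"], charge = g["charge"];
  LogicalVector arom = g["arom"];
  IntegerVector ba = g["ba"], bb = g["bb"], bo = g["bo"];
  LogicalVector barom = g["barom"];
  m.n = elem.size();
  m.elem.assign(elem.begin(), elem.end());
  m.charge.assign(charge.begin(), charge.end());
  m.arom.resize(m.n);
  for (int i = 0; i < m.n; ++i) m.arom[i] = arom[i] ? 1 : 0;
  for (int e = 0; e < ba.size(); ++e) {
    int lab = barom[e] ? 0 : bo[e];
    m.edges.push_back({ba[e] - 1, bb[e] - 1, lab});
  }
  m.build_adj();
  return m;
}

List graph_to_list(const Graph& m) {
  IntegerVector elem(m.n), charge(m.n);
  LogicalVector arom(m.n);
  int ne = m.edges.size();
  IntegerVector ba(ne), bb(ne), bo(ne);
  LogicalVector barom(ne);
  for (int i = 0; i < m.n; ++i) {
    elem[i] = m.elem[i];
    charge[i] = m.charge[i];
    arom[i] = m.arom[i] != 0;
  }
  for (int e = 0; e < ne; ++e) {
    ba[e] = m.edges[e][0] + 1;
    bb[e] = m.edges[e][1] + 1;
    bo[e] = m.edges[e][2] == 0 ? 1 : m.edges[e][2];
    barom[e] = m.edges[e][2] == 0;
  }
  return List::create(_["elem"] = elem, _["charge"] = charge, _["arom"] = arom,
                      _["ba"] = ba, _["bb"] = bb, _["bo"] = bo,
                      _["barom"] = barom);
}

// ---------------------------------------------------------------------------
// Canonical code: lexicographically minimal serialization over an
// isomorphism-invariant family of vertex orderings (connected augmentation,
// candidates minimizing (edge-pattern-to-placed, atom colour)).  The full
// serialization encodes atoms and the complete labelled edge list, so equal
// codes imply isomorphic labelled graphs.

struct CanonSearch {
  const Graph* g;
  std::vector<int> best_perm;   // position -> vertex
  std::string best_code;
  bool have_best = false;
  long explored = 0;

  std::string serialize(const std::vector<int>& perm) const {
    std::vector<int> pos(g->n);
    for (int p = 0; p < g->n; ++p) pos[perm[p]] = p;
    std::string s;
    s.reserve(g->n * 6 + g->edges.size() * 9);
    for (int p = 0; p < g->n; ++p) {
      int v = perm[p];
      s += std::to_string(g->elem[v]);
      s += g->arom[v] ? 'a' : '.';
      if (g->charge[v] != 0) {
        s += g->charge[v] > 0 ? '+' : '-';
        s += std::to_string(std::abs(g->charge[v]));
      }
      s += ';';
    }
    std::vector<std::array<int, 3> > el;
    el.reserve(g->edges.size());
    for (const auto& e : g->edges) {
      int a = pos[e[0]], b = pos[e[1]];
      if (a > b) std::swap(a, b);
      el.push_back({a, b, e[2]});
    }
    std::sort(el.begin(), el.end());
    for (const auto& e : el) {
      s += std::to_string(e[0]);
      s += ',';
      s += std::to_string(e[1]);
      s += ':';
      s += std::to_string(e[2]);
      s += '|';
    }
    return s;
  }

  // colour used only to guide candidate selection (must be iso-invariant)
  std::string colour(int v) const {
    std::string s = std::to_string(g->elem[v]);
    s += g->arom[v] ? 'a' : '.';
    s += std::to_string(g->charge[v] + 10);
    s += 'd';
    s += std::to_string(g->adj[v].size());
    return s;
  }

  void extend(std::vector<int>& perm, std::vector<int>& pos) {
    if (explored > 20000) return;  // symmetric pathological graphs: cap search
    int placed = perm.size();
    if (placed == g->n) {
      ++explored;
      std::string code = serialize(perm);
      if (!have_best || code < best_code) {
        best_code = code;
        best_perm = perm;
        have_best = true;
      }
      return;
    }
    // candidates: unplaced vertices adjacent to the placed set (graph is
    // connected so the set is non-empty after the first placement)
    std::vector<int> cands;
    std::vector<std::string> keys;
    std::string minkey;
    for (int v = 0; v < g->n; ++v) {
      if (pos[v] >= 0) continue;
      std::string key;
      bool touches = false;
      std::vector<std::pair<int, int> > back;
      for (const auto& nb : g->adj[v]) {
        if (pos[nb.first] >= 0) {
          touches = true;
          back.push_back({pos[nb.first], g->edges[nb.second][2]});
        }
      }
      if (!touches) continue;
      std::sort(back.begin(), back.end());
      for (const auto& pr : back) {
        key += std::to_string(pr.first);
        key += ':';
        key += std::to_string(pr.second);
        key += ',';
      }
      key += '/';
      key += colour(v);
      if (cands.empty() || key < minkey) minkey = key;
      cands.push_back(v);
      keys.push_back(key);
    }
    for (size_t i = 0; i < cands.size(); ++i) {
      if (keys[i] != minkey) continue;
      int v = cands[i];
      perm.push_back(v);
      pos[v] = placed;
      extend(perm, pos);
      perm.pop_back();
      pos[v] = -1;
    }
  }

  std::string run() {
    if (g->n == 0) return "";
    // start vertices: all with minimal colour
    std::string minc;
    for (int v = 0; v < g->n; ++v) {
      std::string c = colour(v);
      if (v == 0 || c < minc) minc = c;
    }
    for (int v = 0; v < g->n; ++v) {
      if (colour(v) != minc) continue;
      std::vector<int> perm{v}, pos(g->n, -1);
      pos[v] = 0;
      extend(perm, pos);
    }
    return best_code;
  }
};

std::string canonical_code(const Graph& g, std::vector<int>* perm_out = nullptr) {
  CanonSearch cs;
  cs.g = &g;
  std::string code = cs.run();
  if (perm_out) *perm_out = cs.best_perm;
  return code;
}

// relabel a graph into its canonical vertex order
Graph canonical_graph(const Graph& g) {
  std::vector<int> perm;
  canonical_code(g, &perm);
  Graph out;
  out.n = g.n;
  std::vector<int> pos(g.n);
  for (int p = 0; p < g.n; ++p) pos[perm[p]] = p;
  out.elem.resize(g.n);
  out.charge.resize(g.n);
  out.arom.resize(g.n);
  for (int v = 0; v < g.n; ++v) {
    out.elem[pos[v]] = g.elem[v];
    out.charge[pos[v]] = g.charge[v];
    out.arom[pos[v]] = g.arom[v];
  }
  for (const auto& e : g.edges) {
    int a = pos[e[0]], b = pos[e[1]];
    if (a > b) std::swap(a, b);
    out.edges.push_back({a, b, e[2]});
  }
  std::sort(out.edges.begin(), out.edges.end());
  out.build_adj();
  return out;
}

// ---------------------------------------------------------------------------
// Ring perception: all minimal rings (edge sets) through each ring bond.

// shortest path length between a and b avoiding edge eid; -1 if none
int sp_len_avoiding(const Graph& g, int a, int b, int eid) {
  std::vector<int> dist(g.n, -1);
  std::queue<int> q;
  dist[a] = 0;
  q.push(a);
  while (!q.empty()) {
    int v = q.front();
    q.pop();
    if (v == b) return dist[v];
    for (const auto& nb : g.adj[v]) {
      if (nb.second == eid) continue;
      if (dist[nb.first] < 0) {
        dist[nb.first] = dist[v] + 1;
        q.push(nb.first);
      }
    }
  }
  return -1;
}

// enumerate all paths a->b of exactly length L avoiding eid (L is the
// shortest-path length, so this is a layered DAG walk; counts are tiny)
void all_min_paths(const Graph& g, int a, int b, int eid, int L,
                   std::vector<std::vector<int> >& paths_edges) {
  std::vector<int> distb(g.n, -1);
  std::queue<int> q;
  distb[b] = 0;
  q.push(b);
  while (!q.empty()) {
    int v = q.front();
    q.pop();
    for (const auto& nb : g.adj[v]) {
      if (nb.second == eid) continue;
      if (distb[nb.first] < 0) {
        distb[nb.first] = distb[v] + 1;
        q.push(nb.first);
      }
    }
  }
  std::vector<int> cur;
  std::function<void(int, int)> walk = [&](int v, int d) {
    if ((int)paths_edges.size() > 64) return;  // safety cap
    if (v == b) {
      paths_edges.push_back(cur);
      return;
    }
    for (const auto& nb : g.adj[v]) {
      if (nb.second == eid) continue;
      if (distb[nb.first] == L - d - 1) {
        cur.push_back(nb.second);
        walk(nb.first, d + 1);
        cur.pop_back();
      }
    }
  };
  walk(a, 0);
}

// units: each unit is an edge set; bridge bonds give singleton units, each
// minimal ring gives one unit.  ring_bond[e] = true if e lies on a cycle.
struct Units {
  std::vector<std::vector<int> > unit_edges;
  std::vector<char> ring_bond;                     // per edge
  std::vector<std::vector<int> > rings_through;    // per edge: unit ids of its minimal rings
};

Units perceive_units(const Graph& g) {
  Units u;
  int ne = g.edges.size();
  u.ring_bond.assign(ne, 0);
  u.rings_through.assign(ne, {});
  std::set<std::vector<int> > seen_rings;
  for (int e = 0; e < ne; ++e) {
    int a = g.edges[e][0], b = g.edges[e][1];
    int L = sp_len_avoiding(g, a, b, e);
    if (L < 0) continue;  // bridge
    u.ring_bond[e] = 1;
    std::vector<std::vector<int> > paths;
    all_min_paths(g, a, b, e, L, paths);
    for (auto& p : paths) {
      p.push_back(e);
      std::sort(p.begin(), p.end());
      if (seen_rings.insert(p).second) u.unit_edges.push_back(p);
    }
  }
  // map each ring bond to the minimal rings that contain it and have minimal
  // size among rings through that bond
  for (int e = 0; e < ne; ++e) {
    if (!u.ring_bond[e]) continue;
    size_t best = SIZE_MAX;
    for (size_t r = 0; r < u.unit_edges.size(); ++r) {
      const auto& re = u.unit_edges[r];
      if (std::binary_search(re.begin(), re.end(), e)) best = std::min(best, re.size());
    }
    for (size_t r = 0; r < u.unit_edges.size(); ++r) {
      const auto& re = u.unit_edges[r];
      if (re.size() == best && std::binary_search(re.begin(), re.end(), e))
        u.rings_through[e].push_back(r);
    }
  }
  // bridge bonds become singleton units (after rings so ring ids above hold)
  for (int e = 0; e < ne; ++e)
    if (!u.ring_bond[e]) u.unit_edges.push_back({e});
  return u;
}

// extract subgraph induced by an edge set (plus resulting vertices)
Graph edge_subgraph(const Graph& g, const std::vector<int>& es,
                    std::vector<int>* vmap_out = nullptr) {
  std::vector<int> vmap(g.n, -1);
  Graph s;
  for (int e : es) {
    for (int k = 0; k < 2; ++k) {
      int v = g.edges[e][k];
      if (vmap[v] < 0) {
        vmap[v] = s.n++;
        s.elem.push_back(g.elem[v]);
        s.charge.push_back(g.charge[v]);
        s.arom.push_back(g.arom[v]);
      }
    }
  }
  for (int e : es)
    s.edges.push_back({vmap[g.edges[e][0]], vmap[g.edges[e][1]], g.edges[e][2]});
  s.build_adj();
  if (vmap_out) *vmap_out = vmap;
  return s;
}

// ring-completeness of an edge set: every ring bond present must have one of
// its minimal rings fully inside the set
bool ring_complete(const Units& u, const std::set<int>& es) {
  for (int e : es) {
    if (!u.ring_bond[e]) continue;
    bool ok = false;
    for (int r : u.rings_through[e]) {
      bool all_in = true;
      for (int re : u.unit_edges[r])
        if (!es.count(re)) {
          all_in = false;
          break;
        }
      if (all_in) {
        ok = true;
        break;
      }
    }
    if (!ok) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// VF2-style subgraph monomorphism: does fragment f embed in molecule m?

bool atom_compat(const Graph& f, int fv, const Graph& m, int mv) {
  return f.elem[fv] == m.elem[mv] && f.charge[fv] == m.charge[mv] &&
         f.arom[fv] == m.arom[mv];
}

bool match_from(const Graph& f, const Graph& m, const std::vector<int>& order,
                std::vector<int>& map, std::vector<char>& used, size_t k) {
  if (k == order.size()) return true;
  int fv = order[k];
  // collect constraints: edges from fv to already-mapped fragment vertices
  std::vector<std::pair<int, int> > req;  // (mapped mol vertex, edge label)
  for (const auto& nb : f.adj[fv])
    if (map[nb.first] >= 0) req.push_back({map[nb.first], f.edges[nb.second][2]});
  // candidate molecule vertices
  if (!req.empty()) {
    int anchor = req[0].first;
    for (const auto& mnb : m.adj[anchor]) {
      int mv = mnb.first;
      if (used[mv] || m.edges[mnb.second][2] != req[0].second) continue;
      if (!atom_compat(f, fv, m, mv)) continue;
      if (m.adj[mv].size() < f.adj[fv].size()) continue;
      bool ok = true;
      for (size_t r = 1; r < req.size(); ++r) {
        bool found = false;
        for (const auto& mnb2 : m.adj[mv])
          if (mnb2.first == req[r].first && m.edges[mnb2.second][2] == req[r].second) {
            found = true;
            break;
          }
        if (!found) {
          ok = false;
          break;
        }
      }
      if (!ok) continue;
      map[fv] = mv;
      used[mv] = 1;
      if (match_from(f, m, order, map, used, k + 1)) return true;
      map[fv] = -1;
      used[mv] = 0;
    }
  } else {
    for (int mv = 0; mv < m.n; ++mv) {
      if (used[mv] || !atom_compat(f, fv, m, mv)) continue;
      if (m.adj[mv].size() < f.adj[fv].size()) continue;
      map[fv] = mv;
      used[mv] = 1;
      if (match_from(f, m, order, map, used, k + 1)) return true;
      map[fv] = -1;
      used[mv] = 0;
    }
  }
  return false;
}

bool embeds(const Graph& f, const Graph& m) {
  if (f.n > m.n || f.edges.size() > m.edges.size()) return false;
  // BFS order over the (connected) fragment so each vertex after the first is
  // constrained by at least one mapped neighbour
  std::vector<int> order;
  std::vector<char> seen(f.n, 0);
  if (f.n == 0) return true;
  order.push_back(0);
  seen[0] = 1;
  for (size_t i = 0; i < order.size(); ++i)
    for (const auto& nb : f.adj[order[i]])
      if (!seen[nb.first]) {
        seen[nb.first] = 1;
        order.push_back(nb.first);
      }
  std::vector<int> map(f.n, -1);
  std::vector<char> used(m.n, 0);
  return match_from(f, m, order, map, used, 0);
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported interface

// [[Rcpp::export(name = ".cpp_canonical_code")]]
CharacterVector cpp_canonical_code(List graphs) {
  int n = graphs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    Graph g = graph_from_list(graphs[i]);
    out[i] = canonical_code(g);
  }
  return out;
}

// Enumerate all connected ring-complete subgraphs (1..max_atoms heavy atoms)
// of each molecule; return the global candidate table with per-candidate
// parent links (remove-one-unit connected subfragments) and per-molecule
// candidate membership.
// [[Rcpp::export(name = ".cpp_enumerate_fragments")]]
List cpp_enumerate_fragments(List mols, int max_atoms, int max_subgraphs_per_mol) {
  int nm = mols.size();
  std::map<std::string, int> code_id;          // canonical code -> candidate id
  std::vector<std::string> codes;
  std::vector<Graph> defs;
  std::vector<int> natoms;
  std::vector<std::set<int> > parents;         // candidate id -> parent ids
  std::vector<std::vector<int> > mol_members(nm);

  for (int mi = 0; mi < nm; ++mi) {
    Graph g = graph_from_list(mols[mi]);
    Units u = perceive_units(g);
    int nu = u.unit_edges.size();

    // unit adjacency (shared atom)
    std::vector<std::set<int> > unit_atoms(nu);
    for (int ui = 0; ui < nu; ++ui)
      for (int e : u.unit_edges[ui]) {
        unit_atoms[ui].insert(g.edges[e][0]);
        unit_atoms[ui].insert(g.edges[e][1]);
      }
    std::vector<std::vector<int> > unadj(nu);
    for (int a = 0; a < nu; ++a)
      for (int b = a + 1; b < nu; ++b) {
        bool share = false;
        for (int v : unit_atoms[a])
          if (unit_atoms[b].count(v)) {
            share = true;
            break;
          }
        if (share) {
          unadj[a].push_back(b);
          unadj[b].push_back(a);
        }
      }

    // local records: edge-set key -> local subgraph info
    struct Local {
      std::set<int> units;
      std::set<int> edges;
      int id = -1;  // global candidate id (if kept)
    };
    std::map<std::vector<int>, Local> locals;  // key: sorted edge ids
    long count = 0;
    bool truncated = false;

    // register a unit subset; returns iterator or end if dropped
    auto consider = [&](const std::set<int>& us) {
      std::set<int> es;
      for (int ui : us)
        for (int e : u.unit_edges[ui]) es.insert(e);
      std::set<int> vs;
      for (int e : es) {
        vs.insert(g.edges[e][0]);
        vs.insert(g.edges[e][1]);
      }
      if ((int)vs.size() > max_atoms) return;
      if (!ring_complete(u, es)) return;
      std::vector<int> key(es.begin(), es.end());
      if (locals.count(key)) {
        // same edge set reached via a different unit subset: keep the first
        return;
      }
      Local L;
      L.units = us;
      L.edges = es;
      Graph sub = edge_subgraph(g, key);
      std::string code = canonical_code(sub);
      auto it = code_id.find(code);
      int id;
      if (it == code_id.end()) {
        id = codes.size();
        code_id[code] = id;
        codes.push_back(code);
        defs.push_back(canonical_graph(sub));
        natoms.push_back(sub.n);
        parents.push_back({});
      } else {
        id = it->second;
      }
      L.id = id;
      locals[key] = L;
    };

    // ESU over the unit graph: every connected unit subset exactly once
    std::function<void(std::set<int>&, std::vector<int>&, int)> extend_esu =
        [&](std::set<int>& sub, std::vector<int>& ext, int v0) {
          if (truncated) return;
          if (++count > max_subgraphs_per_mol) {
            truncated = true;
            return;
          }
          // atom-count pruning: supersets only grow
          std::set<int> vs;
          for (int ui : sub)
            for (int v : unit_atoms[ui]) vs.insert(v);
          if ((int)vs.size() > max_atoms) return;
          consider(sub);
          std::vector<int> ext_local = ext;
          while (!ext_local.empty()) {
            int w = ext_local.back();
            ext_local.pop_back();
            std::vector<int> ext2 = ext_local;
            for (int nb : unadj[w]) {
              if (nb <= v0 || sub.count(nb)) continue;
              bool already = false;
              // exclusive neighbourhood test (cheap sizes; linear scan)
              for (int s : sub)
                for (int nb2 : unadj[s])
                  if (nb2 == nb) {
                    already = true;
                    break;
                  }
              if (!already &&
                  std::find(ext2.begin(), ext2.end(), nb) == ext2.end())
                ext2.push_back(nb);
            }
            sub.insert(w);
            extend_esu(sub, ext2, v0);
            sub.erase(w);
          }
        };

    for (int v0 = 0; v0 < nu && !truncated; ++v0) {
      std::set<int> sub{v0};
      std::vector<int> ext;
      for (int nb : unadj[v0])
        if (nb > v0) ext.push_back(nb);
      extend_esu(sub, ext, v0);
    }
    if (truncated)
      Rf_warning("subgraph enumeration truncated for molecule %d (cap %d)",
                 mi + 1, max_subgraphs_per_mol);

    // single-atom candidates
    std::set<int> seen_atom_ids;
    for (int v = 0; v < g.n; ++v) {
      Graph s;
      s.n = 1;
      s.elem = {g.elem[v]};
      s.charge = {g.charge[v]};
      s.arom = {g.arom[v]};
      s.build_adj();
      std::string code = canonical_code(s);
      auto it = code_id.find(code);
      int id;
      if (it == code_id.end()) {
        id = codes.size();
        code_id[code] = id;
        codes.push_back(code);
        defs.push_back(s);
        natoms.push_back(1);
        parents.push_back({});
      } else {
        id = it->second;
      }
      seen_atom_ids.insert(id);
    }

    // membership for this molecule
    std::set<int> members(seen_atom_ids);
    for (const auto& kv : locals) members.insert(kv.second.id);
    mol_members[mi].assign(members.begin(), members.end());

    // parent links: remove one unit, keep connectivity
    for (const auto& kv : locals) {
      const Local& L = kv.second;
      if (L.units.size() == 1) {
        // parents are the single atoms of this unit
        Graph sub = edge_subgraph(g, kv.first);
        for (int v = 0; v < sub.n; ++v) {
          Graph s;
          s.n = 1;
          s.elem = {sub.elem[v]};
          s.charge = {sub.charge[v]};
          s.arom = {sub.arom[v]};
          s.build_adj();
          auto it = code_id.find(canonical_code(s));
          if (it != code_id.end()) parents[L.id].insert(it->second);
        }
        continue;
      }
      for (int ui : L.units) {
        std::set<int> rest = L.units;
        rest.erase(ui);
        // connectivity of 'rest' on the unit graph
        std::set<int> seen;
        std::queue<int> q;
        q.push(*rest.begin());
        seen.insert(*rest.begin());
        while (!q.empty()) {
          int v = q.front();
          q.pop();
          for (int nb : unadj[v])
            if (rest.count(nb) && !seen.count(nb)) {
              seen.insert(nb);
              q.push(nb);
            }
        }
        if (seen.size() != rest.size()) continue;
        std::set<int> es;
        for (int ru : rest)
          for (int e : u.unit_edges[ru]) es.insert(e);
        std::vector<int> key(es.begin(), es.end());
        auto it = locals.find(key);
        if (it != locals.end() && it->second.id >= 0)
          parents[L.id].insert(it->second.id);
      }
    }
  }

  int nc = codes.size();
  CharacterVector rcodes(nc);
  IntegerVector rnatoms(nc);
  List rdefs(nc), rparents(nc);
  for (int i = 0; i < nc; ++i) {
    rcodes[i] = codes[i];
    rnatoms[i] = natoms[i];
    rdefs[i] = graph_to_list(defs[i]);
    IntegerVector p(parents[i].size());
    int k = 0;
    for (int pid : parents[i]) p[k++] = pid + 1;
    rparents[i] = p;
  }
  List rmembers(nm);
  for (int mi = 0; mi < nm; ++mi) {
    IntegerVector mm(mol_members[mi].size());
    for (size_t k = 0; k < mol_members[mi].size(); ++k)
      mm[k] = mol_members[mi][k] + 1;
    rmembers[mi] = mm;
  }
  return List::create(_["code"] = rcodes, _["n_atoms"] = rnatoms,
                      _["graph"] = rdefs, _["parents"] = rparents,
                      _["members"] = rmembers);
}

// ---------------------------------------------------------------------------
// Hashed circular (Morgan/extended-connectivity style) fingerprints on the
// heavy-atom graph.  Initial atom invariant: element, formal charge,
// aromaticity, degree and bond-order sum (hydrogen-agnostic); each
// iteration hashes the atom invariant with the sorted (bond label,
// neighbour invariant) list.  Every invariant at every radius sets one bit
// (invariant mod n_bits).  Deterministic across platforms.

static inline uint32_t mix(uint32_t h, uint32_t v) {
  h ^= v + 0x9e3779b9u + (h << 6) + (h >> 2);
  return h;
}

// [[Rcpp::export(name = ".cpp_ecfp")]]
IntegerMatrix cpp_ecfp(List mols, int n_bits, int radius) {
  int nm = mols.size();
  IntegerMatrix out(nm, n_bits);
  for (int mi = 0; mi < nm; ++mi) {
    RObject g0 = mols[mi];
    if (g0.isNULL()) continue;
    Graph g = graph_from_list(List(g0));
    std::vector<uint32_t> inv(g.n), nxt(g.n);
    for (int v = 0; v < g.n; ++v) {
      uint32_t h = 2166136261u;
      h = mix(h, (uint32_t)g.elem[v]);
      h = mix(h, (uint32_t)(g.charge[v] + 16));
      h = mix(h, (uint32_t)(g.arom[v] ? 1 : 0));
      h = mix(h, (uint32_t)g.adj[v].size());
      int bsum = 0;
      for (const auto& nb : g.adj[v])
        bsum += g.edges[nb.second][2] == 0 ? 15 : 10 * g.edges[nb.second][2];
      h = mix(h, (uint32_t)bsum);
      inv[v] = h;
      out(mi, h % n_bits) = 1;
    }
    for (int r = 1; r <= radius; ++r) {
      for (int v = 0; v < g.n; ++v) {
        std::vector<std::pair<uint32_t, uint32_t> > nbrs;
        for (const auto& nb : g.adj[v])
          nbrs.push_back({(uint32_t)(g.edges[nb.second][2]), inv[nb.first]});
        std::sort(nbrs.begin(), nbrs.end());
        uint32_t h = 0x811c9dc5u;
        h = mix(h, (uint32_t)r);
        h = mix(h, inv[v]);
        for (const auto& p : nbrs) {
          h = mix(h, p.first);
          h = mix(h, p.second);
        }
        nxt[v] = h;
        out(mi, h % n_bits) = 1;
      }
      inv = nxt;
    }
  }
  return out;
}

// number of distinct minimal rings per molecule, total and fully aromatic
// [[Rcpp::export(name = ".cpp_ring_counts")]]
IntegerMatrix cpp_ring_counts(List mols) {
  int nm = mols.size();
  IntegerMatrix out(nm, 2);
  colnames(out) = CharacterVector::create("rings", "aromatic_rings");
  for (int i = 0; i < nm; ++i) {
    Graph g = graph_from_list(mols[i]);
    Units u = perceive_units(g);
    int nr = 0, na = 0;
    for (const auto& ue : u.unit_edges) {
      if (ue.size() < 3) continue;  // bridge units
      ++nr;
      bool all_arom = true;
      for (int e : ue)
        if (g.edges[e][2] != 0) {
          all_arom = false;
          break;
        }
      if (all_arom) ++na;
    }
    out(i, 0) = nr;
    out(i, 1) = na;
  }
  return out;
}

// logical matrix [n_frags x n_mols]: does fragment i embed in molecule j?
// [[Rcpp::export(name = ".cpp_match_matrix")]]
LogicalMatrix cpp_match_matrix(List frags, List mols) {
  int nf = frags.size(), nm = mols.size();
  std::vector<Graph> fg(nf), mg(nm);
  for (int i = 0; i < nf; ++i) fg[i] = graph_from_list(frags[i]);
  for (int j = 0; j < nm; ++j) mg[j] = graph_from_list(mols[j]);
  LogicalMatrix out(nf, nm);
  for (int j = 0; j < nm; ++j) {
    for (int i = 0; i < nf; ++i) out(i, j) = embeds(fg[i], mg[j]);
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// support counts: for each fragment, number of molecules with >=1 embedding
// [[Rcpp::export(name = ".cpp_support_counts")]]
IntegerVector cpp_support_counts(List frags, List mols) {
  int nf = frags.size(), nm = mols.size();
  std::vector<Graph> fg(nf), mg(nm);
  for (int i = 0; i < nf; ++i) fg[i] = graph_from_list(frags[i]);
  for (int j = 0; j < nm; ++j) mg[j] = graph_from_list(mols[j]);
  IntegerVector out(nf);
  for (int i = 0; i < nf; ++i) {
    int c = 0;
    for (int j = 0; j < nm; ++j)
      if (embeds(fg[i], mg[j])) ++c;
    out[i] = c;
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
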
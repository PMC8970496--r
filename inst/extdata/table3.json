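[
  {
    "name": "Hierarchical (Ward's)",
    "family": "hierarchical",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "no",
      "variable_cluster_density": "yes",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "yes",
      "multimodal_hierarchical": "yes"
    },
    "parameters": ["k"],
    "deterministic": "yes",
    "complexity": "n^2 log n"
  },
  {
    "name": "Hierarchical (Single Link)",
    "family": "hierarchical",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "yes",
      "variable_cluster_density": "no",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "no",
      "multimodal_hierarchical": "yes"
    },
    "parameters": ["k"],
    "deterministic": "yes",
    "complexity": "n^2 log n"
  },
  {
    "name": "BIRCH",
    "family": "hierarchical",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "yes",
      "non_spherical_shape": "no",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "yes",
      "multimodal_hierarchical": "yes"
    },
    "parameters": ["k", "threshold", "branching_factor"],
    "deterministic": "unknown",
    "complexity": "n"
  },
  {
    "name": "k-means",
    "family": "partition",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "no",
      "variable_cluster_density": "no",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "no",
      "robust_noise_outliers": "no",
      "multimodal_hierarchical": "no"
    },
    "parameters": ["k"],
    "deterministic": "no",
    "complexity": "n k d i"
  },
  {
    "name": "k-means minibatch",
    "family": "partition",
    "support": {
      "small_datasets": "no",
      "high_dimensions": "yes",
      "non_spherical_shape": "no",
      "variable_cluster_density": "no",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "no",
      "robust_noise_outliers": "no",
      "multimodal_hierarchical": "no"
    },
    "parameters": ["k", "batch_size"],
    "deterministic": "no",
    "complexity": {"level": "n k d i", "caveat": "sub-nkdi in practice (mini-batches)"}
  },
  {
    "name": "PAM",
    "family": "partition",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "no",
      "variable_cluster_density": "no",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "yes",
      "multimodal_hierarchical": "no"
    },
    "parameters": ["k"],
    "deterministic": "no",
    "complexity": "n^2 k^2"
  },
  {
    "name": "Fuzzy C-Means",
    "family": "partition",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "no",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "no",
      "robust_noise_outliers": "no",
      "multimodal_hierarchical": "no"
    },
    "parameters": ["k"],
    "deterministic": "no",
    "complexity": "n k^2 d i"
  },
  {
    "name": "DBSCAN",
    "family": "density",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "yes",
      "variable_cluster_density": "no",
      "single_point_cluster": {"level": "yes", "caveat": "enabling single point clustering removes outlier/noise detection"},
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "yes",
      "multimodal_hierarchical": "no"
    },
    "parameters": ["eps", "min_samples"],
    "deterministic": {"level": "yes", "caveat": "results can change based on the order the data is provided"},
    "complexity": "n log n"
  },
  {
    "name": "HDBSCAN",
    "family": "density",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "yes",
      "variable_cluster_density": "yes",
      "single_point_cluster": {"level": "yes", "caveat": "enabling single point clustering removes outlier/noise detection"},
      "robust_noise_outliers": "yes",
      "multimodal_hierarchical": {"level": "yes", "caveat": "hierarchy inferable from condensed tree"}
    },
    "parameters": ["min_cluster_size", "min_samples"],
    "deterministic": "yes",
    "complexity": "n^2"
  },
  {
    "name": "OPTICS",
    "family": "density",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "yes",
      "variable_cluster_density": "yes",
      "single_point_cluster": "no",
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "yes",
      "multimodal_hierarchical": {"level": "yes", "caveat": "hierarchy inferable from reachability plot"}
    },
    "parameters": ["min_samples", "eps_cl"],
    "deterministic": {"level": "yes", "caveat": "results can change based on the order the data is provided"},
    "complexity": "n"
  },
  {
    "name": "Mean Shift",
    "family": "density",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "yes",
      "variable_cluster_density": "no",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "yes",
      "multimodal_hierarchical": {"level": "yes", "caveat": "hierarchy inferable from bandwidth sweep"}
    },
    "parameters": ["bandwidth"],
    "deterministic": "unknown",
    "complexity": "n^2"
  },
  {
    "name": "Spectral Clustering",
    "family": "graph/spectral",
    "support": {
      "small_datasets": "no",
      "high_dimensions": "yes",
      "non_spherical_shape": "yes",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "no",
      "robust_noise_outliers": "no",
      "multimodal_hierarchical": "no"
    },
    "parameters": ["k", "n_neighbors"],
    "deterministic": "no",
    "complexity": "n^3"
  },
  {
    "name": "Affinity Propagation",
    "family": "graph/spectral",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "yes",
      "non_spherical_shape": "yes",
      "variable_cluster_density": "no",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "no",
      "multimodal_hierarchical": {"level": "yes", "caveat": "hierarchy inferable from exemplar graph"}
    },
    "parameters": ["damping", "preference"],
    "deterministic": "unknown",
    "complexity": {"level": "n^2 i", "caveat": "often printed as n^2; iterative message passing places it strictly above n^2 for selection purposes"}
  },
  {
    "name": "Gaussian Mixture Model",
    "family": "model-based",
    "support": {
      "small_datasets": "yes",
      "high_dimensions": "no",
      "non_spherical_shape": "yes",
      "variable_cluster_density": "yes",
      "single_point_cluster": "yes",
      "uneven_cluster_size": "yes",
      "robust_noise_outliers": "yes",
      "multimodal_hierarchical": "no"
    },
    "parameters": ["k"],
    "deterministic": "no",
    "complexity": "n k d^3"
  }
]
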
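pdb_id,site,aa_elect,aa_vdw,aa_total,cg_elect,cg_vdw,cg_total
1GMN,1,-3354.6,-42.2,-92.6,-3625.8,-53.2,-98.8
1HM2,1,-458.6,-47.2,-22.4,-539.4,-61.7,-80.6
1LOH,1,-42.5,-76.5,-55.6,-103.3,-31.8,-109.8
1OFM,1,-746.5,-27.7,-42.1,-767.2,-27.2,-50.9
2D8L,1,-30.7,-25.3,-5.5,-44.9,-35.1,-40.2
2NWG,1,-1737.9,-22.4,-55.5,-2334.1,-33.5,-94.4
2NWG,2,-1096.7,-21.5,-25.1,-1158.5,-35.4,-57.9
3ANK,1,3.9,-41.0,-22.1,-83.7,-52.9,-88.6
3OGX,1,-1235.8,-53.9,-51.6,-1351.7,-54.3,-57.3
3OJV,1,-5701.5,-86.0,-194.9,-5978.7,-88.4,-233.2
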
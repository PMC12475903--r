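cultivar,species
Barbera,vinifera
Cabernet Franc,vinifera
Cabernet Sauvignon,vinifera
Chardonnay,vinifera
Dolcetto,vinifera
Gewurztraminer,vinifera
Gruner Veltliner,vinifera
Lemberger,vinifera
Malbec,vinifera
Merlot,vinifera
Nebbiolo,vinifera
Pinot Gris,vinifera
Pinot Noir,vinifera
Riesling,vinifera
Sangiovese,vinifera
Sauvignon Blanc,vinifera
Semillon,vinifera
Syrah,vinifera
Tempranillo,vinifera
Viognier,vinifera
Zinfandel,vinifera
Aravelle,hybrid
Baco Noir,hybrid
Brianna,hybrid
Cascade,hybrid
Catawba,hybrid
Cayuga White,hybrid
Chambourcin,hybrid
Chancellor,hybrid
Chelois,hybrid
Concord,hybrid
Corot Noir,hybrid
DeChaunac,hybrid
Delaware,hybrid
Edelweiss,hybrid
Frontenac,hybrid
Frontenac Gris,hybrid
Geneva Red,hybrid
Itasca,hybrid
La Crescent,hybrid
La Crosse,hybrid
Leon Millot,hybrid
Marechal Foch,hybrid
Marquette,hybrid
Niagara,hybrid
Noiret,hybrid
Norton,hybrid
Petite Pearl,hybrid
Seyval Blanc,hybrid
St. Croix,hybrid
Traminette,hybrid
Valvin Muscat,hybrid
Vidal Blanc,hybrid
Vignoles,hybrid
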